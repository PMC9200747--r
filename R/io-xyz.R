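# Extended-XYZ dataset dialect.  Per frame:
#   line 1: atom count
#   line 2: key=value pairs (e0, e1, isomer, provenance, h01 presence flag)
#   then one line per atom: symbol x y z f0x f0y f0z f1x f1y f1z [h01x h01y h01z]
# Floats are written with "%.12g", giving round trips well inside 1e-8
# relative precision.  Parsing is locale-independent (C-style decimal point).

.fmt <- function(x) sprintf("%.12g", x)

#' Write a labeled dataset to an extended-XYZ file
#'
#' @param frames list of [labeled_frame()] objects (may be empty)
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(frames, path) {
  stopifnot(is.list(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    if (!inherits(fr, "dann_frame")) stop("frames must be dann_frame objects")
    g <- fr$geometry
    n <- n_atoms(g)
    has_h <- !is.null(fr$h01)
    writeLines(as.character(n), con)
    writeLines(sprintf("e0=%s e1=%s isomer=%s provenance=%s h01=%d",
                       .fmt(fr$e0), .fmt(fr$e1), g$isomer, fr$provenance,
                       as.integer(has_h)), con)
    body <- cbind(g$pos, fr$f0, fr$f1)
    if (has_h) body <- cbind(body, fr$h01)
    lines <- paste(element_symbol(g$z),
                   apply(body, 1, function(r) paste(.fmt(r), collapse = " ")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a labeled dataset from an extended-XYZ file
#'
#' Every frame is validated against the labeled-frame invariants
#' (`e1 >= e0`, matching shapes, finite values); a violation raises an error
#' naming the frame index.  Frame order is preserved.
#'
#' @param path dataset file written by [write_dataset()] (or compatible)
#' @return list of [labeled_frame()] objects
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    idx <- idx + 1L
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n < 2)
      stop(sprintf("frame %d: bad atom count line '%s'", idx, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("frame %d: truncated frame", idx))
    hdr <- .parse_kv(lines[i + 1L], idx)
    need <- c("e0", "e1", "isomer", "provenance", "h01")
    if (!all(need %in% names(hdr)))
      stop(sprintf("frame %d: missing header keys: %s", idx,
                   paste(setdiff(need, names(hdr)), collapse = ", ")))
    has_h <- as.integer(hdr[["h01"]]) == 1L
    ncol_exp <- 9L + if (has_h) 3L else 0L
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    if (any(lengths(rows) != ncol_exp + 1L))
      stop(sprintf("frame %d: expected %d columns per atom", idx, ncol_exp + 1L))
    sym <- vapply(rows, `[[`, "", 1L)
    num <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))), nrow = n,
                  byrow = TRUE)
    if (!all(is.finite(num)))
      stop(sprintf("frame %d: non-finite values", idx))
    fr <- tryCatch(
      labeled_frame(
        geometry(symbol_to_z(sym), num[, 1:3, drop = FALSE],
                 isomer = hdr[["isomer"]]),
        e0 = as.numeric(hdr[["e0"]]), e1 = as.numeric(hdr[["e1"]]),
        f0 = num[, 4:6, drop = FALSE], f1 = num[, 7:9, drop = FALSE],
        h01 = if (has_h) num[, 10:12, drop = FALSE] else NULL,
        provenance = hdr[["provenance"]]),
      error = function(e) stop(sprintf("frame %d: %s", idx, conditionMessage(e)),
                               call. = FALSE))
    frames[[idx]] <- fr
    i <- i + 2L + n
  }
  frames
}

.parse_kv <- function(line, idx) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  kv <- regmatches(toks, regexec("^([A-Za-z0-9_]+)=(.*)$", toks))
  if (any(lengths(kv) != 3))
    stop(sprintf("frame %d: malformed header token", idx))
  stats::setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
}

#' Write a surface-hopping trajectory as multi-frame XYZ
#'
#' Each frame's comment line records the time (fs), the active surface and
#' the adiabatic energies, so the file is self-describing and viewable in
#' standard molecular viewers.
#'
#' @param result a `dann_trajectory` from [run_trajectory()]
#' @param path output path
#' @param stride keep every `stride`-th stored frame
#' @return `path`, invisibly
#' @export
write_trajectory <- function(result, path, stride = 1L) {
  if (!inherits(result, "dann_trajectory")) stop("result must be a dann_trajectory")
  if (length(result$frames) < 1) stop("empty trajectory")
  keep <- seq(1L, length(result$frames), by = as.integer(stride))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in keep) {
    fr <- result$frames[[k]]
    writeLines(as.character(length(fr$z)), con)
    writeLines(sprintf("t=%s active=%d e0=%s e1=%s", .fmt(fr$t), fr$active,
                       .fmt(fr$e0), .fmt(fr$e1)), con)
    writeLines(paste(element_symbol(fr$z),
                     apply(fr$pos, 1, function(r) paste(.fmt(r), collapse = " "))),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory written by [write_trajectory()]
#'
#' @param path trajectory file
#' @return list with per-frame times, active surfaces, energies and positions
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(lines[i])
    hdr <- .parse_kv(lines[i + 1L], length(out) + 1L)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    num <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))), nrow = n, byrow = TRUE)
    out[[length(out) + 1L]] <- list(
      t = as.numeric(hdr[["t"]]), active = as.integer(hdr[["active"]]),
      e0 = as.numeric(hdr[["e0"]]), e1 = as.numeric(hdr[["e1"]]),
      z = symbol_to_z(vapply(rows, `[[`, "", 1L)), pos = num[, 1:3, drop = FALSE])
    i <- i + 2L + n
  }
  out
}
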