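# MRtrix .tck streamline files.  TCK stores points in world (scanner) mm,
# which is exactly this package's tractogram convention, so no coordinate
# transform is ever applied: what is read is what was tracked.
# Format: a text header ("mrtrix tracks" + key: value lines + "END"), then
# float32 triplets; streamlines are separated by NaN triplets and the stream
# is terminated by an Inf triplet.

#' Write a tractogram to a .tck file
#'
#' @param tractogram a [tractogram] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(tractogram, path) {
  stopifnot(inherits(tractogram, "tractogram"))
  sl <- tractogram$streamlines
  hdr_lines <- c(
    "mrtrix tracks",
    "datatype: Float32LE",
    sprintf("count: %d", length(sl)),
    sprintf("step_size: %g", tractogram$nominal_step_mm),
    "dwiphantom: 1"
  )
  # 'file: . <offset>' must state its own byte offset; fix by iteration.
  offset <- 0L
  for (i in 1:6) {
    file_line <- sprintf("file: . %d", offset)
    total <- sum(nchar(c(hdr_lines, file_line, "END"), type = "bytes")) +
      length(hdr_lines) + 2L          # newlines
    if (total == offset) break
    offset <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr_lines, sprintf("file: . %d", offset), "END"), con, sep = "\n")
  nan3 <- rep(NaN, 3)
  for (s in sl) {
    writeBin(as.double(t(s)), con, size = 4L, endian = "little")
    writeBin(nan3, con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a .tck streamline file
#'
#' Streamlines with fewer than 2 points are dropped with a message; an empty
#' file yields an empty tractogram with a warning.
#'
#' @param path a `.tck` file.
#' @param nominal_step_mm override for the nominal step size; default is the
#'   `step_size` header entry when present, else the observed mean step.
#' @return a [tractogram].
#' @export
read_tractogram <- function(path, nominal_step_mm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first) || !grepl("^mrtrix tracks", first))
    stop("not an MRtrix .tck file (bad magic line): ", path)
  meta <- list()
  offset <- NA_real_
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unterminated .tck header in ", path)
    if (line == "END") break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  if (!is.null(meta$datatype) && !identical(meta$datatype, "Float32LE"))
    stop("unsupported .tck datatype '", meta$datatype,
         "' (only Float32LE is handled)")
  if (is.null(meta$file))
    stop(".tck header lacks the mandatory 'file' entry: ", path)
  offset <- as.numeric(sub("^\\.\\s+", "", meta$file))
  if (is.na(offset)) stop("unparsable .tck 'file' offset: ", meta$file)
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "double", n = file.size(path), size = 4L,
                  endian = "little")
  if (length(vals) %% 3 != 0)
    stop("corrupt .tck stream (length not a multiple of 3)")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- apply(is.nan(pts), 1, any)
  is_end <- apply(is.infinite(pts), 1, any)
  end_at <- which(is_end)[1]
  if (is.na(end_at)) stop("missing .tck end-of-stream marker")
  pts <- pts[seq_len(end_at - 1L), , drop = FALSE]
  is_sep <- is_sep[seq_len(end_at - 1L)]
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)])) # streamline ids
  keep <- !is_sep
  sl <- if (any(keep)) {
    unname(lapply(split.data.frame(pts[keep, , drop = FALSE], grp[keep]),
                  function(m) `dimnames<-`(as.matrix(m), NULL)))
  } else list()
  short <- vapply(sl, nrow, 0L) < 2L
  if (any(short)) {
    message(sum(short), " streamline(s) with < 2 points dropped")
    sl <- sl[!short]
  }
  if (!length(sl)) warning("empty tractogram read from ", path)
  if (is.null(nominal_step_mm)) {
    nominal_step_mm <- if (!is.null(meta$step_size)) {
      as.numeric(meta$step_size)
    } else if (length(sl)) {
      mean(unlist(lapply(sl, function(s)
        sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))))
    } else NA_real_
  }
  tractogram(sl, nominal_step_mm = nominal_step_mm, validate = length(sl) > 0)
}
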