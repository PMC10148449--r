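# PennCNV-style rawcnv text round-trip. One call per line:
#   chrN:start-end numsnp=K length=L,bp state=S,cn=C SAMPLE
#   startsnp=ID endsnp=ID conf=X
# State codes follow the PennCNV convention: 1 = cn0, 2 = cn1, 5 = cn3,
# 6 = cn4 (diploid is never a call).

CN_TO_STATE <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)

#' Write calls to a rawcnv text file
#' @param calls call data frame ([viterbi_call()] shape).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rawcnv <- function(calls, path) {
  assert_that(all(calls$copy_state %in% c(0L, 1L, 3L, 4L)),
              "diploid (cn=2) records cannot be written as calls")
  lines <- sprintf("%s:%d-%d numsnp=%d length=%d,bp state=%d,cn=%d %s startsnp=%s endsnp=%s conf=%.4f",
                   calls$chrom, calls$start_bp, calls$end_bp, calls$n_probes,
                   calls$length_bp, CN_TO_STATE[as.character(calls$copy_state)],
                   calls$copy_state, calls$sample_id, calls$start_probe,
                   calls$end_probe,
                   ifelse(is.na(calls$conf), 0, calls$conf))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rawcnv text file
#' @param path rawcnv file.
#' @return call data frame; empty file gives zero rows.
#' @export
read_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_calls())
  pat <- paste0("^(\\S+):(\\d+)-(\\d+)\\s+numsnp=(\\d+)\\s+length=(\\d+),bp\\s+",
                "state=(\\d+),cn=(\\d+)\\s+(\\S+)\\s+startsnp=(\\S+)\\s+",
                "endsnp=(\\S+)\\s+conf=(\\S+)\\s*$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, 1L) == 0)
  if (length(bad) > 0)
    stop_arg("malformed rawcnv line ", bad[1], " in ", path, ": ", lines[bad[1]])
  f <- function(i) vapply(m, `[[`, character(1), i + 1L)
  cn <- as.integer(f(7))
  if (any(cn == 2L)) {
    bad <- which(cn == 2L)[1]
    stop_arg("rawcnv line ", bad, " has cn=2; diploid is not a call")
  }
  if (any(!cn %in% c(0L, 1L, 3L, 4L)))
    stop_arg("rawcnv file has copy states outside {0,1,3,4}")
  data.frame(sample_id = f(8), chrom = f(1),
             start_bp = as.integer(f(2)), end_bp = as.integer(f(3)),
             start_probe = f(9), end_probe = f(10),
             n_probes = as.integer(f(4)), copy_state = cn,
             length_bp = as.integer(f(5)), conf = as.numeric(f(11)),
             stringsAsFactors = FALSE)
}
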