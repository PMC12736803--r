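# Minimal MEME motif format reader/writer (probability matrices only).

#' Write motifs in MEME minimal format
#'
#' @param pwms named list of position probability matrices (rows = positions,
#'   columns = A, C, G, T; rows sum to 1).
#' @param path output file.
#' @param background length-4 background frequencies (A, C, G, T).
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2],
                       background[3], background[4]), ""), con)
  for (id in names(pwms)) {
    m <- pwms[[id]]
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", nrow(m)),
      con)
    writeLines(apply(m, 1, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                               r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' @param path MEME file as written by [write_meme()] (or any minimal-format
#'   file with letter-probability matrices over ACGT).
#' @return named list of position probability matrices with columns A,C,G,T
#'   and attribute `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bi <- grep("^Background letter frequencies", lines)
  if (length(bi)) {
    toks <- strsplit(trimws(lines[bi[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + 1
    while (h <= length(lines) && !grepl("letter-probability matrix", lines[h]))
      h <- h + 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- do.call(rbind, lapply(rows, function(x)
      as.numeric(strsplit(trimws(x), "\\s+")[[1]])))
    colnames(m) <- c("A", "C", "G", "T")
    pwms[[id]] <- m
  }
  attr(pwms, "background") <- bg
  pwms
}
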