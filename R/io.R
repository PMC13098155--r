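# Plain TSV I/O with a one-line header, plus the MaxQuant
# modification-specific-peptides dialect mapping.

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# MaxQuant header <-> canonical column names
.mq_map <- c(sequence = "Sequence", modifications = "Modifications",
             missed_cleavages = "Missed cleavages", proteins = "Proteins",
             unique = "Unique")

#' Write a peptide table in the MaxQuant dialect
#'
#' Canonical columns are renamed to the MaxQuant
#' modification-specific-peptides headers (`Sequence`, `Modifications`,
#' `Missed cleavages`, `Proteins`, `Unique`) and the intensity columns to
#' `Intensity <sample>`.
#'
#' @param peptides canonical peptide data.frame (see [top3()]).
#' @param path output TSV.
#' @export
write_peptide_table <- function(peptides, path) {
  out <- peptides
  for (canon in names(.mq_map)) {
    names(out)[names(out) == canon] <- .mq_map[[canon]]
  }
  ints <- grep("^intensity_", names(out))
  names(out)[ints] <- paste("Intensity", sub("^intensity_", "", names(out)[ints]))
  write_tsv(out, path)
}

#' Read a MaxQuant-dialect peptide table into canonical columns
#'
#' @param path TSV with MaxQuant modification-specific-peptides headers.
#' @return Canonical peptide data.frame.
#' @export
read_peptide_table <- function(path) {
  x <- read_tsv(path)
  for (canon in names(.mq_map)) {
    names(x)[names(x) == .mq_map[[canon]]] <- canon
  }
  ints <- grep("^Intensity ", names(x))
  names(x)[ints] <- paste0("intensity_", sub("^Intensity ", "", names(x)[ints]))
  if (is.character(x$unique)) {
    x$unique <- x$unique %in% c("TRUE", "yes", "Yes", "+", "1")
  }
  x
}
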