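#' Published species confusion matrix from the NEON-NIST challenge test set
#'
#' The 9-species crown-classification confusion matrix (rows = predicted,
#' columns = reference, 126 test crowns) reported for the Ordway-Swisher
#' Biological Station site of the NEON-NIST data science evaluation
#' challenge.  Species codes: ACRU *Acer rubrum*, LIST *Liquidambar
#' styraciflua*, PIEL *Pinus elliottii*, PIPA *P. palustris*, PITA
#' *P. taeda*, QUGE *Quercus geminata*, QULA *Q. laevis*, QUNI *Q. nigra*,
#' OTHER unidentifiable.  Useful as a worked example for
#' [confusion_metrics()].
#'
#' @return Integer matrix with dimnames (predicted, reference).
#' @export
osbs_species_confusion <- function() {
  path <- system.file("extdata", "osbs_species_confusion.csv",
                      package = "canopyseg", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$predicted
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("predicted", "reference")
  m
}
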