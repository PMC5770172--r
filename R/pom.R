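#' Construct a population of models
#'
#' A population of models (POM) is a set of parameter vectors for one
#' underlying model together with the biomarker outputs each produces.
#'
#' @param theta Numeric matrix of parameter vectors (rows = members).
#' @param biomarkers Numeric matrix of outputs, same row count.
#' @param provenance List of calibration metadata (method, seed, settings).
#' @return Object of class `pom`.
#' @export
pom <- function(theta, biomarkers, provenance = list()) {
  theta <- as.matrix(theta)
  biomarkers <- as.matrix(biomarkers)
  if (nrow(theta) != nrow(biomarkers))
    stop("theta and biomarkers must have the same number of rows")
  structure(list(theta = theta, biomarkers = biomarkers,
                 provenance = provenance), class = "pom")
}

#' @export
print.pom <- function(x, ...) {
  cat(sprintf("Population of models: %d members, %d parameters, %d biomarkers\n",
              nrow(x$theta), ncol(x$theta), ncol(x$biomarkers)))
  if (length(x$provenance))
    cat("provenance:", paste(names(x$provenance),
                             vapply(x$provenance, function(v)
                               paste(format(v), collapse = " "), ""),
                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.pom <- function(x) nrow(x$theta)

#' Subset a population of models by member index
#' @param x A [pom()].
#' @param idx Integer or logical member index.
#' @return A `pom` with the selected members.
#' @export
subset_pom <- function(x, idx) {
  pom(x$theta[idx, , drop = FALSE], x$biomarkers[idx, , drop = FALSE],
      x$provenance)
}

#' @export
as.data.frame.pom <- function(x, ...) {
  data.frame(x$theta, x$biomarkers, check.names = FALSE)
}
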