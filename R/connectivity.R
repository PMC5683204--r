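# Connectivity matrices: N x N weighted graphs over atlas labels, either
# functional (correlation-like, signed) or structural (streamline counts,
# nonnegative).

#' Construct and validate a connectivity matrix
#'
#' A connectivity matrix is an N x N weighted adjacency matrix over atlas
#' regions. On construction it is validated and canonicalised: it must be
#' square with N >= 2 and all entries finite; structural matrices must be
#' nonnegative; an asymmetric matrix is symmetrised by averaging with its
#' transpose (with a warning) when the asymmetry exceeds `tol`; and the
#' diagonal is forced to zero, because self-connections carry no meaning for
#' node-strength scores (the functional diagonal is an artefactual 1.0).
#'
#' @param values square numeric matrix of edge weights.
#' @param labels integer atlas labels, one per row/column. Defaults to the
#'   integer prefix of the dimnames when present, else `seq_len(N)`.
#' @param flavour `"functional"` (signed weights) or `"structural"`
#'   (nonnegative fibre counts).
#' @param tol asymmetry tolerance; `max |A - t(A)|` above this triggers
#'   symmetrisation by `(A + t(A)) / 2` with a warning.
#' @return An object of class `connectivity_matrix`: a list with `values`
#'   (validated matrix, dimnames set to the labels), `labels` (integer
#'   vector) and `flavour`.
#' @export
connectivity_matrix <- function(values, labels = NULL,
                                flavour = c("functional", "structural"),
                                tol = 1e-8) {
  flavour <- match.arg(flavour)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square, got ",
         nrow(values), " x ", ncol(values))
  n <- nrow(values)
  if (n < 2L) stop("connectivity matrix needs at least 2 regions")
  storage.mode(values) <- "double"
  if (any(is.na(values)))
    stop("connectivity matrix contains NA/NaN entries")
  if (any(!is.finite(values)))
    stop("connectivity matrix contains non-finite entries")
  if (flavour == "structural" && any(values < 0))
    stop("structural connectivity entries must be nonnegative")

  if (is.null(labels)) {
    nm <- rownames(values)
    if (!is.null(nm)) {
      parsed <- suppressWarnings(as.integer(sub("^[^0-9-]*", "", nm)))
      labels <- if (any(is.na(parsed)) || anyDuplicated(parsed)) seq_len(n)
                else parsed
    } else {
      labels <- seq_len(n)
    }
  }
  labels <- as.integer(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be ", n, " unique integers")

  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    warning(sprintf(
      "asymmetric %s matrix (max |A - t(A)| = %.3g); symmetrised by averaging",
      flavour, asym))
    values <- (values + t(values)) / 2
  }
  diag(values) <- 0
  dimnames(values) <- list(as.character(labels), as.character(labels))

  structure(list(values = values, labels = labels, flavour = flavour),
            class = "connectivity_matrix")
}

#' Read a connectivity matrix from delimited text
#'
#' Expects a square table with one header row and one header column of atlas
#' labels. The delimiter (comma or tab) is auto-detected from the first line.
#' The loaded matrix passes through [connectivity_matrix()] validation:
#' diagonal zeroed, symmetrised if needed, nonnegativity enforced for
#' structural matrices.
#'
#' @param path path to a CSV/TSV matrix file.
#' @param flavour `"functional"` or `"structural"`.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path, flavour = c("functional", "structural")) {
  flavour <- match.arg(flavour)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop("connectivity file contains non-numeric entries: ", path)
  if (nrow(m) != ncol(m))
    stop("connectivity file is not a square labelled table: ", path,
         " (", nrow(m), " x ", ncol(m), ")")
  connectivity_matrix(m, flavour = flavour)
}

#' Write a connectivity matrix as delimited text
#'
#' @param cm a `connectivity_matrix`.
#' @param path output file path.
#' @param sep field delimiter, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path, sep = ",") {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$values, path, sep = sep, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d regions (labels %s..%s)\n",
              x$flavour, length(x$labels),
              min(x$labels), max(x$labels)))
  invisible(x)
}
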