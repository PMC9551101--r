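#' Named gene (or miRNA) set
#'
#' A lightweight container for a disease gene list, a background universe, or
#' a set of miRNA identifiers. Duplicates are removed (first occurrence kept)
#' so the set semantics the enrichment urns assume always hold.
#'
#' @param name set name, e.g. an HPO term id or `"SCZ_GWAS"`.
#' @param genes character vector of identifiers.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L)
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " ids\n", sep = "")
  if (length(x$genes))
    cat(" ", paste(utils::head(x$genes, 8), collapse = ", "),
        if (length(x$genes) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
as.character.gene_set <- function(x, ...) x$genes
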