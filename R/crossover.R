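#' Build the enrichment urn for one screen
#'
#' Restricts the disease list and every miRNA's target set to a common gene
#' universe. The universe defaults to all genes appearing in the target
#' table; pass an explicit background [gene_set] to override. Identifiers
#' outside the universe are reported, never silently dropped.
#'
#' @param targets a [target_table].
#' @param disease a [gene_set] of disease-associated genes.
#' @param background optional [gene_set]; the gene universe.
#' @return A list with `universe` (character), `disease` (genes of the list
#'   present in the universe), `targets` (the table restricted to the
#'   universe) and `discarded` (list of ids dropped from each input).
#' @export
build_universe <- function(targets, disease, background = NULL) {
  stopifnot(inherits(targets, "target_table"), inherits(disease, "gene_set"))
  universe <- if (is.null(background)) unique(targets$gene_id)
              else background$genes
  if (length(universe) == 0) stop("empty gene universe")
  disc_dis <- setdiff(disease$genes, universe)
  dis <- intersect(disease$genes, universe)
  if (length(dis) == 0)
    stop("no gene of disease list '", disease$name,
         "' is in the universe; the crossover test is undefined")
  keep <- targets$gene_id %in% universe
  list(universe = universe,
       disease = dis,
       targets = targets[keep, , drop = FALSE],
       discarded = list(disease = disc_dis,
                        targets = unique(targets$gene_id[!keep])))
}

#' Odds parameter from target prediction scores
#'
#' Reduces a miRNA's target scores to the odds multiplier of the noncentral
#' urn: the mean prediction score of its targets inside the disease list
#' divided by the mean score of its targets outside it. With uniform scores,
#' or when either group is empty, the ratio is 1 and the test reduces to the
#' central hypergeometric.
#'
#' @param scores numeric prediction scores of one miRNA's universe targets.
#' @param in_disease logical, same length: is each target in the disease
#'   list?
#' @return A positive scalar odds parameter.
#' @examples
#' omega_from_scores(c(90, 90, 60, 60, 60), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
omega_from_scores <- function(scores, in_disease) {
  stopifnot(length(scores) == length(in_disease))
  if (!any(in_disease) || all(in_disease)) return(1)
  mean(scores[in_disease]) / mean(scores[!in_disease])
}

#' Crossover probability of one miRNA's target set
#'
#' The upper-tail Fisher's-noncentral-hypergeometric probability of the
#' observed overlap between a miRNA's predicted targets and a disease gene
#' list, with the odds parameter carrying the target-score weighting.
#'
#' @param N,K,n,k urn counts: universe size, disease genes in universe,
#'   targets in universe, overlap.
#' @param omega odds parameter (1 = unweighted central test).
#' @param alpha significance bound on the raw p-value (default 0.01).
#' @return A one-row data.frame with the urn, `omega`, `p_value` and
#'   `significant`.
#' @export
crossover_probability <- function(N, K, n, k, omega = 1, alpha = 0.01) {
  p <- fnch_sf(N, K, n, k, omega = omega)
  data.frame(n_universe = N, n_disease_in_universe = K, n_targets = n,
             overlap = k, omega = omega, p_value = p,
             significant = p < alpha)
}

#' Per-miRNA crossover screen against a disease gene list
#'
#' Runs [crossover_probability] for every upregulated miRNA: the urn is the
#' gene universe coloured by the disease list, the draw is the miRNA's
#' predicted target set, and the odds parameter comes from
#' [omega_from_scores] (or is fixed at 1 with `omega_mode = "unit"`). A
#' miRNA with no target in the universe is kept in the output with
#' `p_value = 1` and flagged untestable. Following the raw-p convention of
#' the screen, no multiple-testing correction is applied unless
#' `adjust = TRUE`.
#'
#' @param upregulated [gene_set] of miRNA ids to screen.
#' @param targets a [target_table].
#' @param disease a [gene_set] of disease genes.
#' @param background optional universe [gene_set] (default: all genes in the
#'   target table).
#' @param alpha significance bound (default 0.01, raw p).
#' @param omega_mode `"score_ratio"` (default) or `"unit"`.
#' @param adjust if `TRUE`, flag significance on BH-adjusted p-values.
#' @return A data.frame of class `crossover_screen`, one row per miRNA,
#'   ordered by miRNA id; attribute `disorder` carries the disease-set name.
#' @export
crossover_screen <- function(upregulated, targets, disease,
                             background = NULL, alpha = 0.01,
                             omega_mode = c("score_ratio", "unit"),
                             adjust = FALSE) {
  stopifnot(inherits(upregulated, "gene_set"), length(upregulated) > 0)
  omega_mode <- match.arg(omega_mode)
  urn <- build_universe(targets, disease, background)
  N <- length(urn$universe)
  K <- length(urn$disease)
  by_mirna <- split(urn$targets, urn$targets$mirna_id)
  rows <- lapply(sort(upregulated$genes), function(m) {
    tt <- by_mirna[[m]]
    if (is.null(tt) || nrow(tt) == 0)
      return(data.frame(mirna_id = m, n_universe = N,
                        n_disease_in_universe = K, n_targets = 0L,
                        overlap = 0L, omega = 1, p_value = 1,
                        significant = FALSE, testable = FALSE))
    ind <- tt$gene_id %in% urn$disease
    om <- if (omega_mode == "unit") 1 else omega_from_scores(tt$score, ind)
    res <- crossover_probability(N, K, nrow(tt), sum(ind), omega = om,
                                 alpha = alpha)
    cbind(data.frame(mirna_id = m), res, testable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) {
    out$p_adj <- bh_adjust(out$p_value)$adjusted
    out$significant <- out$p_adj < alpha & out$testable
  }
  class(out) <- c("crossover_screen", "data.frame")
  attr(out, "disorder") <- disease$name
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.crossover_screen <- function(x, ...) {
  cat("Crossover screen vs '", attr(x, "disorder"), "': ",
      sum(x$significant), " of ", nrow(x),
      " miRNAs significant at p < ", attr(x, "alpha"), "\n", sep = "")
  print.data.frame(utils::head(x[order(x$p_value), ], 10))
  invisible(x)
}

#' Significant miRNAs of a crossover screen
#'
#' @param screen a `crossover_screen` data.frame.
#' @return A [gene_set] named after the disorder.
#' @export
associated_mirnas <- function(screen) {
  stopifnot(inherits(screen, "crossover_screen"))
  gene_set(attr(screen, "disorder"),
           sort(screen$mirna_id[screen$significant]))
}

#' Monte-Carlo sensitivity check for one crossover test
#'
#' Generative alternative to the score-ratio odds reduction: target sets of
#' size `n` are drawn from the universe without replacement with selection
#' weight `score/100` for the miRNA's predicted targets and a baseline of
#' 0.5 for all other genes, and the overlap with the disease list is
#' tallied. Intended as a sensitivity check on the default analytic test,
#' not as the screen's engine.
#'
#' @param targets a [target_table] restricted to one miRNA.
#' @param disease,background [gene_set]s (background required here).
#' @param n_draws number of Monte-Carlo draws.
#' @return Empirical upper-tail probability of the observed overlap.
#' @export
crossover_mc <- function(targets, disease, background, n_draws = 10000) {
  stopifnot(inherits(background, "gene_set"))
  urn <- build_universe(targets, disease, background)
  tg <- urn$targets
  n <- nrow(tg)
  if (n == 0) return(1)
  k_obs <- sum(tg$gene_id %in% urn$disease)
  w <- rep(0.5, length(urn$universe))
  w[match(tg$gene_id, urn$universe)] <- tg$score / 100
  is_dis <- urn$universe %in% urn$disease
  k_sim <- vapply(seq_len(n_draws), function(i)
    sum(is_dis[sample.int(length(w), n, prob = w)]), integer(1))
  mean(k_sim >= k_obs)
}
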