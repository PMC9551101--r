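#' Configuration for the synthetic-data generators
#'
#' Defaults emulate a desk-scale two-condition small-RNA experiment:
#' negative-binomial counts with dispersion 0.05, three replicates per
#' condition, log-normal library sizes around 5e6 reads, log-normal baseline
#' abundances, and miRDB-convention target tables with scores in [50, 100].
#' Planted upregulated miRNAs receive a fixed, well-expressed baseline mean
#' (qPCR-validated miRNAs are rarely near the detection floor) multiplied by
#' their true fold change in the treated condition. All generators are pure
#' functions of `seed`.
#'
#' @param n_mirnas number of miRNAs in the count matrix.
#' @param n_per_group replicates per condition.
#' @param mean_meanlog,mean_sdlog log-normal parameters of baseline miRNA
#'   mean counts.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param planted_up data.frame with columns `index`, `fc`: miRNAs truly
#'   upregulated in the treated condition and their fold changes.
#' @param planted_base_mean baseline mean count of planted miRNAs.
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param mirna_length mature length in nt assigned to every miRNA.
#' @param n_genes size of the simulated gene universe.
#' @param targets_per_mirna predicted targets per miRNA (default 100,
#'   keeping the miRDB-scale proportion of targets to universe at the
#'   desk-scale universe size).
#' @param score_bounds target prediction score range.
#' @param disease_size genes per simulated disease list.
#' @param planted_enriched indices of miRNAs whose target sets are enriched
#'   for disease genes.
#' @param enrichment_multiplier sampling-weight multiplier for disease genes
#'   in planted target sets (1 = null).
#' @param score_shift additive score shift for disease-listed targets
#'   (capped at the upper score bound).
#' @param seed integer seed fixing every generated object.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 200, n_per_group = 3,
                       mean_meanlog = log(50), mean_sdlog = 1.5,
                       nb_dispersion = 0.05,
                       planted_up = data.frame(index = integer(),
                                               fc = numeric()),
                       planted_base_mean = 200,
                       lib_meanlog = log(5e6), lib_sdlog = 0.2,
                       mirna_length = 22,
                       n_genes = 1000, targets_per_mirna = 100,
                       score_bounds = c(50, 100), disease_size = 100,
                       planted_enriched = integer(),
                       enrichment_multiplier = 5, score_shift = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_mirnas > 0, cfg$n_per_group > 0, cfg$n_genes > 0,
            cfg$nb_dispersion >= 0, cfg$targets_per_mirna > 0,
            all(cfg$planted_up$fc > 1),
            all(cfg$planted_up$index <= cfg$n_mirnas))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-condition miRNA count matrix
#'
#' Negative-binomial counts for `n_mirnas` miRNAs across two conditions.
#' Baseline means are log-normal; each sample's counts are scaled by its
#' relative library depth; planted miRNAs have their treated mean multiplied
#' by the configured true fold change.
#'
#' @param cfg a [sim_config].
#' @return A [count_matrix] with conditions `control` / `treated`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_mirnas; r <- cfg$n_per_group
  base <- stats::rlnorm(n, cfg$mean_meanlog, cfg$mean_sdlog)
  base[cfg$planted_up$index] <- cfg$planted_base_mean
  fc <- rep(1, n)
  fc[cfg$planted_up$index] <- cfg$planted_up$fc
  lib <- stats::rlnorm(2 * r, cfg$lib_meanlog, cfg$lib_sdlog)
  depth <- lib / exp(cfg$lib_meanlog)
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  counts <- sapply(seq_len(2 * r), function(s) {
    mu <- base * depth[s] * (if (s > r) fc else 1)
    if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
    else stats::rpois(n, mu)
  })
  dimnames(counts) <- list(sprintf("mir-%04d", seq_len(n)),
                           c(sprintf("ctrl_%d", seq_len(r)),
                             sprintf("trt_%d", seq_len(r))))
  count_matrix(counts,
               rep(c("control", "treated"), each = r),
               cfg$mirna_length)
}

#' Simulate a target table and disease gene lists
#'
#' Draws each miRNA's predicted target set from a synthetic gene universe.
#' For planted disorder-associated miRNAs, disease-listed genes are
#' oversampled by `enrichment_multiplier`; other miRNAs sample uniformly
#' (the null of the crossover screen). Scores are uniform over
#' `score_bounds`, with an optional upward shift for disease-listed targets.
#'
#' @param cfg a [sim_config].
#' @return A list: `targets` ([target_table]), `disease` ([gene_set]
#'   `"disease_sim"`), `background` ([gene_set] of the full universe).
#' @export
simulate_targets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  disease <- sort(sample(genes, cfg$disease_size))
  w_base <- rep(1, cfg$n_genes)
  w_enr <- w_base
  w_enr[genes %in% disease] <- cfg$enrichment_multiplier
  rows <- lapply(seq_len(cfg$n_mirnas), function(i) {
    w <- if (i %in% cfg$planted_enriched) w_enr else w_base
    tg <- sample(genes, cfg$targets_per_mirna, prob = w)
    sc <- stats::runif(cfg$targets_per_mirna,
                       cfg$score_bounds[1], cfg$score_bounds[2])
    sc <- pmin(sc + cfg$score_shift * (tg %in% disease),
               cfg$score_bounds[2])
    data.frame(mirna_id = sprintf("mir-%04d", i), gene_id = tg,
               score = round(sc, 1))
  })
  list(targets = target_table(do.call(rbind, rows),
                              score_bounds = cfg$score_bounds),
       disease = gene_set("disease_sim", disease),
       background = gene_set("universe", genes))
}

# deterministic membership layout reproducing the published set
# cardinalities: 56 upregulated; |ID|=43, |SCZ|=34, |ASD|=15 with ASD
# inside ID and |ASD & SCZ|=13; 11 REST-targeting with overlaps 11/10/5
# and the 5 ASD members forming the named core set
fixture_memberships <- function() {
  core <- c("miR-26a", "miR-26b", "miR-153", "miR-181a", "miR-548")
  sim <- sprintf("mirSIM-%03d", 1:51)
  trip <- c(core, sim[1:8])       # ID & SCZ & ASD (13)
  id_asd <- sim[9:10]             # ID & ASD only (2)
  id_scz <- sim[11:23]            # ID & SCZ only (13), REST: first 5
  id_only <- sim[24:38]           # ID only (15), REST: first 1
  scz_only <- sim[39:46]          # SCZ only (8)
  none <- sim[47:51]              # no disorder (5)
  list(up = c(trip, id_asd, id_scz, id_only, scz_only, none),
       id = c(trip, id_asd, id_scz, id_only),
       scz = c(trip, id_scz, scz_only),
       asd = c(trip, id_asd),
       rest = c(core, id_scz[1:5], id_only[1]),
       core = core)
}

#' Deterministic fixture reproducing the published set cardinalities
#'
#' Builds, with no randomness, a complete input bundle — count matrix,
#' target table, disease gene lists, background universe and REST-targeting
#' miRNA list — constructed so that the full pipeline (DE filter at
#' fold change >= 2.5 and BH-adjusted p < 0.05, crossover screen at
#' p < 0.01, convergence tests at p < 0.05) emits exactly the published
#' cardinalities: 56 upregulated miRNAs, disorder sets of 43 (ID), 34 (SCZ)
#' and 15 (ASD), REST overlaps of 11/10/5, and the five-member core set
#' {miR-26a, miR-26b, miR-153, miR-181a, miR-548}.
#'
#' Only those cardinalities and the five core names are anchored to the
#' published analysis; all other identifiers are synthetic (`mirSIM-*`,
#' `mirNULL-*`, `g*`), since the full published miRNA list is not
#' redistributed here. The count matrix carries 444 unchanged miRNAs
#' alongside the 56 upregulated ones so that library-size normalisation
#' leaves the planted fold change well above the threshold. Construction
#' fails loudly if any cardinality constraint is violated.
#'
#' @return A list of class `reference_fixture`: `cm`, `targets`, `disease`
#'   (list of three [gene_set]s), `background`, `rest_mirnas`, `expected`
#'   (the membership layout the pipeline must reproduce).
#' @export
reference_fixture <- function() {
  mem <- fixture_memberships()
  stopifnot(length(mem$up) == 56, length(mem$id) == 43,
            length(mem$scz) == 34, length(mem$asd) == 15,
            all(mem$asd %in% mem$id),
            length(intersect(mem$asd, mem$scz)) == 13,
            length(mem$rest) == 11,
            length(intersect(mem$rest, mem$id)) == 11,
            length(intersect(mem$rest, mem$scz)) == 10,
            length(intersect(mem$rest, mem$asd)) == 5,
            setequal(intersect(mem$rest, mem$asd), mem$core))

  # counts: 56 upregulated 6x + 444 unchanged, deterministic replicate
  # jitter so within-group variance is positive
  nulls <- sprintf("mirNULL-%03d", 1:444)
  ids <- c(mem$up, nulls)
  base <- 100 + (seq_along(ids) * 7) %% 200
  jit <- c(0.95, 1.00, 1.05)
  up <- ids %in% mem$up
  counts <- cbind(round(outer(base, jit)),
                  round(outer(base * ifelse(up, 6, 1), jit)))
  dimnames(counts) <- list(ids, c(sprintf("ctrl_%d", 1:3),
                                  sprintf("trt_%d", 1:3)))
  cm <- count_matrix(counts, rep(c("control", "treated"), each = 3), 22)

  # gene universe: three disjoint 100-gene disease blocks, 700 background
  # genes, plus the shared target gene REST
  genes <- sprintf("g%04d", 1:1000)
  blocks <- list(id = genes[1:100], scz = genes[101:200],
                 asd = genes[201:300])
  bg_pool <- genes[301:1000]
  universe <- c(genes, "REST")

  # each upregulated miRNA: 8 genes from each disorder block it belongs
  # to, background fill to 25 targets, plus REST for the 11 REST-targeting
  rows <- lapply(seq_along(mem$up), function(i) {
    m <- mem$up[i]
    tg <- character()
    for (d in c("id", "scz", "asd"))
      if (m %in% mem[[d]])
        tg <- c(tg, blocks[[d]][(((i - 1) * 3 + 0:7) %% 100) + 1])
    tg <- c(tg, bg_pool[(((i - 1) * 5 + seq_len(25 - length(tg)) - 1)
                         %% 700) + 1])
    if (m %in% mem$rest) tg <- c(tg, "REST")
    data.frame(mirna_id = m, gene_id = tg, score = 80)
  })
  targets <- target_table(do.call(rbind, rows))

  fx <- structure(
    list(cm = cm, targets = targets,
         disease = list(gene_set("HP:0001249", blocks$id),
                        gene_set("SCZ_GWAS", blocks$scz),
                        gene_set("HP:0000717", blocks$asd)),
         background = gene_set("universe", universe),
         rest_mirnas = gene_set("REST_targeting", mem$rest),
         expected = mem),
    class = "reference_fixture")
  fx
}

#' @export
print.reference_fixture <- function(x, ...) {
  cat("Deterministic pipeline fixture:\n")
  cat("  counts:", nrow(x$cm$counts), "miRNAs x", ncol(x$cm$counts),
      "samples\n")
  cat("  targets:", nrow(x$targets), "records,",
      length(unique(x$targets$mirna_id)), "miRNAs\n")
  cat("  disease lists:", paste(vapply(x$disease, function(s) s$name,
                                       character(1)), collapse = ", "), "\n")
  cat("  REST-targeting miRNAs:", length(x$rest_mirnas), "\n")
  invisible(x)
}

#' Write fixture or simulated inputs to a directory
#'
#' Emits `counts.tsv`, `samples.tsv`, `lengths.tsv`, `targets.tsv`,
#' `disease.gmt`, `background.txt` and `rest_mirnas.txt` so the pipeline
#' can be driven from files.
#'
#' @param fx a `reference_fixture` (or a list with the same components).
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  write_count_matrix(fx$cm, dir)
  write_target_table(fx$targets, file.path(dir, "targets.tsv"))
  write_gmt(fx$disease, file.path(dir, "disease.gmt"))
  write_id_list(fx$background, file.path(dir, "background.txt"))
  write_id_list(fx$rest_mirnas, file.path(dir, "rest_mirnas.txt"))
  invisible(dir)
}
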