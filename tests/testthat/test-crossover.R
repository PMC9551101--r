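toy_targets <- function() {
  target_table(data.frame(
    mirna_id = rep(c("mirA", "mirB"), each = 5),
    gene_id = c(paste0("g", 1:5), paste0("g", 4:8)),
    score = c(90, 90, 60, 60, 60, rep(70, 5))))
}

test_that("build_universe counts the urn and reports discards", {
  tt <- toy_targets()
  bg <- gene_set("bg", paste0("g", 1:10))
  dis <- gene_set("dz", c("g1", "g2", "g11", "g12", "g13"))
  urn <- build_universe(tt, dis, bg)
  expect_equal(length(urn$universe), 10)
  expect_equal(sort(urn$disease), c("g1", "g2"))
  expect_setequal(urn$discarded$disease, c("g11", "g12", "g13"))
  expect_equal(nrow(urn$targets), 10)  # all targets inside bg
  # disease disjoint from universe is an error
  expect_error(build_universe(tt, gene_set("dz2", "g99"), bg),
               "undefined")
  # default universe = genes of the target table
  urn2 <- build_universe(tt, dis)
  expect_equal(length(urn2$universe), 8)
})

test_that("omega is the ratio of mean scores with unit fallback", {
  expect_equal(omega_from_scores(c(90, 90, 60, 60, 60),
                                 c(TRUE, TRUE, FALSE, FALSE, FALSE)), 1.5)
  expect_equal(omega_from_scores(rep(80, 4), c(TRUE, TRUE, FALSE, FALSE)),
               1)
  expect_equal(omega_from_scores(c(90, 60), c(FALSE, FALSE)), 1)
  expect_equal(omega_from_scores(c(90, 60), c(TRUE, TRUE)), 1)
})

test_that("crossover_probability wires the urn into the noncentral tail", {
  res <- crossover_probability(4, 2, 2, 2, omega = 2)
  expect_equal(res$p_value, 4 / 13)
  expect_false(res$significant)
  expect_equal(crossover_probability(56, 43, 11, 11)$p_value,
               0.0386294, tolerance = 1e-5)
  # omega = 1 equals the central upper tail
  expect_equal(crossover_probability(100, 20, 15, 6)$p_value,
               hypergeom_sf(100, 20, 15, 6))
})

test_that("crossover screen: central reduction, relabelling and order invariance", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:200)
  tt <- target_table(do.call(rbind, lapply(1:10, function(i)
    data.frame(mirna_id = sprintf("mir%02d", i),
               gene_id = sample(genes, 15), score = 80))))
  dis <- gene_set("dz", sample(genes, 40))
  bg <- gene_set("bg", genes)
  up <- gene_set("up", sprintf("mir%02d", 1:10))

  scr <- crossover_screen(up, tt, dis, bg)
  # uniform scores: identical to a plain hypergeometric screen
  for (i in seq_len(nrow(scr)))
    expect_equal(scr$p_value[i],
                 hypergeom_sf(scr$n_universe[i],
                              scr$n_disease_in_universe[i],
                              scr$n_targets[i], scr$overlap[i]))
  expect_equal(scr$p_value, crossover_screen(up, tt, dis, bg,
                                             omega_mode = "unit")$p_value)

  # permutation of gene identifiers leaves p-values unchanged
  relab <- setNames(sample(genes), genes)
  tt2 <- tt; tt2$gene_id <- unname(relab[tt$gene_id])
  dis2 <- gene_set("dz", unname(relab[dis$genes]))
  bg2 <- gene_set("bg", unname(relab[genes]))
  scr2 <- crossover_screen(up, target_table(tt2), dis2, bg2)
  expect_equal(scr2$p_value, scr$p_value)

  # miRNA processing order does not matter
  up_rev <- gene_set("up", rev(up$genes))
  expect_equal(crossover_screen(up_rev, tt, dis, bg), scr)

  # disease list disjoint from all targets: zero significant
  dis3 <- gene_set("dz3", setdiff(genes, tt$gene_id))
  scr3 <- crossover_screen(up, tt, dis3, bg)
  expect_equal(sum(scr3$significant), 0)

  # miRNA with no targets is kept, untestable, p = 1
  up4 <- gene_set("up", c(up$genes, "mir99"))
  scr4 <- crossover_screen(up4, tt, dis, bg)
  row99 <- scr4[scr4$mirna_id == "mir99", ]
  expect_false(row99$testable)
  expect_equal(row99$p_value, 1)
})

test_that("planted disorder miRNAs are recovered, nulls called near alpha", {
  # generator nulls: significance rate ~ alpha across many null miRNAs
  cfg0 <- sim_config(n_mirnas = 300, enrichment_multiplier = 1, seed = 8)
  sim0 <- simulate_targets(cfg0)
  up0 <- gene_set("up", sprintf("mir-%04d", 1:300))
  scr0 <- crossover_screen(up0, sim0$targets, sim0$disease,
                           sim0$background)
  rate <- mean(scr0$significant)
  # binomial band around alpha = 0.01 over 300 tests
  expect_lt(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / 300))

  # planted: 20 enriched of 56 at the default 5x multiplier
  cfg1 <- sim_config(n_mirnas = 56, planted_enriched = 1:20, seed = 9)
  sim1 <- simulate_targets(cfg1)
  up1 <- gene_set("up", sprintf("mir-%04d", 1:56))
  scr1 <- crossover_screen(up1, sim1$targets, sim1$disease,
                           sim1$background)
  sens <- mean(scr1$significant[match(sprintf("mir-%04d", 1:20),
                                      scr1$mirna_id)])
  expect_gte(sens, 0.8)
})

test_that("Monte-Carlo sensitivity check agrees with the analytic screen", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:60)
  tt <- target_table(data.frame(mirna_id = "mirA",
                                gene_id = genes[1:12], score = 80))
  dis <- gene_set("dz", genes[1:20])
  bg <- gene_set("bg", genes)
  p_mc <- crossover_mc(tt, dis, bg, n_draws = 4000)
  p_an <- hypergeom_sf(60, 20, 12, 12)
  # same direction of evidence at a coarse level: both near-extreme
  expect_lt(abs(p_mc - p_an), 0.1)
})
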