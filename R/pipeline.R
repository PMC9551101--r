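#' Run the full analysis pipeline
#'
#' Orchestrates the stages on one input bundle: differential expression and
#' the upregulation filter, one crossover screen per disease gene list, the
#' second-level convergence test of the shared-target (REST-targeting)
#' miRNAs within each disorder-associated set, and the three-disorder Venn
#' decomposition with core-set extraction.
#'
#' The convergence universe is the upregulated survivor set (the population
#' both the disorder sets and the shared-target set are drawn from); pass
#' `universe = "all"` to use every miRNA in the count matrix instead.
#' Shared-target miRNAs outside the chosen universe are dropped with a note
#' in the report.
#'
#' @param inputs a [reference_fixture], a directory of pipeline files (as
#'   written by [write_fixture]), or a list with components `cm`,
#'   `targets`, `disease` (list of [gene_set]s), `background` (or `NULL`)
#'   and `rest_mirnas`.
#' @param fc_threshold,alpha_de survivor filter thresholds (defaults 2.5
#'   and 0.05).
#' @param alpha_crossover raw-p bound of the per-miRNA screen (default
#'   0.01).
#' @param alpha_convergence bound of the second-level test (default 0.05).
#' @param test DE engine passed to [de_test].
#' @param omega_mode odds construction passed to [crossover_screen].
#' @param universe `"upregulated"` (default) or `"all"`.
#' @param outdir if non-NULL, stage artifacts (TSV) and a JSON report are
#'   written here.
#' @param verbose emit one machine-greppable `[mircross]` log line per
#'   stage.
#' @return A list of class `mircross_report`.
#' @export
run_all <- function(inputs, fc_threshold = 2.5, alpha_de = 0.05,
                    alpha_crossover = 0.01, alpha_convergence = 0.05,
                    test = "nb_wald",
                    omega_mode = c("score_ratio", "unit"),
                    universe = c("upregulated", "all"),
                    outdir = NULL, verbose = TRUE) {
  omega_mode <- match.arg(omega_mode)
  universe <- match.arg(universe)
  if (is.character(inputs) && length(inputs) == 1L)
    inputs <- read_pipeline_inputs(inputs)
  say <- function(...) if (verbose) message("[mircross] ", sprintf(...))

  de <- de_test(inputs$cm, test = test)
  up <- apply_cutoffs(de, fc_threshold = fc_threshold, alpha = alpha_de)
  say("stage=de in=%d out=%d", nrow(de), length(up))
  if (length(up) == 0) stop("stage de: no miRNA passed the filter")

  screens <- lapply(inputs$disease, function(ds)
    crossover_screen(up, inputs$targets, ds,
                     background = inputs$background,
                     alpha = alpha_crossover, omega_mode = omega_mode))
  names(screens) <- vapply(inputs$disease, function(s) s$name, character(1))
  disorder_sets <- lapply(screens, associated_mirnas)
  for (nm in names(screens))
    say("stage=crossover disorder=%s in=%d out=%d", nm,
        nrow(screens[[nm]]), length(disorder_sets[[nm]]))

  uni <- if (universe == "upregulated") up
         else gene_set("all_mirnas", rownames(inputs$cm$counts))
  rest_all <- inputs$rest_mirnas
  rest <- gene_set(rest_all$name, intersect(rest_all$genes, uni$genes))
  dropped_rest <- setdiff(rest_all$genes, uni$genes)
  conv <- do.call(rbind, lapply(disorder_sets, function(ds)
    convergence_test(uni, ds, rest, alpha = alpha_convergence)))
  rownames(conv) <- NULL
  class(conv) <- c("convergence_result", "data.frame")
  say("stage=converge in=%d out=%d significant=%d", length(uni),
      nrow(conv), sum(conv$significant))

  sets_in_rest <- lapply(disorder_sets, function(ds)
    gene_set(ds$name, intersect(ds$genes, rest$genes)))
  venn <- venn_decompose(sets_in_rest, rest)
  core <- core_set(venn)
  say("stage=venn in=%d core=%d", length(rest), length(core))

  report <- structure(
    list(de = de, upregulated = up, screens = screens,
         disorder_sets = disorder_sets, convergence = conv,
         venn = venn, core = core, dropped_rest = dropped_rest,
         config = list(fc_threshold = fc_threshold, alpha_de = alpha_de,
                       alpha_crossover = alpha_crossover,
                       alpha_convergence = alpha_convergence, test = test,
                       omega_mode = omega_mode, universe = universe),
         counts = list(n_mirnas = nrow(de), n_upregulated = length(up),
                       disorder_sizes = lengths(disorder_sets),
                       n_rest = length(rest), core_size = length(core)),
         checksums = input_checksums(inputs),
         version = as.character(utils::packageVersion("mircross"))),
    class = "mircross_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.mircross_report <- function(x, ...) {
  cat("mircross pipeline report (v", x$version, ")\n", sep = "")
  cat(" ", x$counts$n_mirnas, "miRNAs ->", x$counts$n_upregulated,
      "upregulated survivors\n")
  cat("  disorder-associated:",
      paste(sprintf("%s=%d", names(x$counts$disorder_sizes),
                    x$counts$disorder_sizes), collapse = ", "), "\n")
  print(x$convergence)
  cat("  core set (", length(x$core), "): ",
      paste(x$core$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

read_pipeline_inputs <- function(dir) {
  sets <- read_gmt(file.path(dir, "disease.gmt"))
  bg_file <- file.path(dir, "background.txt")
  list(cm = read_count_matrix(file.path(dir, "counts.tsv"),
                              file.path(dir, "samples.tsv"),
                              file.path(dir, "lengths.tsv")),
       targets = read_target_table(file.path(dir, "targets.tsv")),
       disease = unname(sets),
       background = if (file.exists(bg_file))
         gene_set("universe", read_id_list(bg_file)) else NULL,
       rest_mirnas = gene_set("REST_targeting",
                              read_id_list(file.path(dir,
                                                     "rest_mirnas.txt"))))
}

# md5 of a canonical text serialisation of the inputs, so the report
# checksum changes iff the inputs change
input_checksums <- function(inputs) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(list(counts = unname(inputs$cm$counts),
            condition = as.character(inputs$cm$condition),
            lengths = unname(inputs$cm$lengths),
            targets = as.data.frame(inputs$targets),
            disease = lapply(inputs$disease, function(s) s$genes),
            background = if (is.null(inputs$background)) NULL
                         else inputs$background$genes,
            rest = inputs$rest_mirnas$genes),
       file = f, control = "all")
  unname(tools::md5sum(f))
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$de, file.path(outdir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_id_list(report$upregulated, file.path(outdir, "upregulated.txt"))
  for (nm in names(report$screens))
    utils::write.table(report$screens[[nm]],
                       file.path(outdir, paste0("crossover_",
                                                gsub("[^A-Za-z0-9]", "_",
                                                     nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$convergence,
                     file.path(outdir, "convergence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = report$config, counts = report$counts,
         convergence = report$convergence,
         venn = as.list(report$venn$counts),
         core = report$core$genes, dropped_rest = report$dropped_rest,
         checksums = report$checksums, version = report$version),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

#' Read a flat key-value run configuration
#'
#' One `key: value` pair per line (a YAML-compatible subset); `#` comments
#' and blank lines ignored. Numeric-looking values are converted. Values
#' given in `overrides` (e.g. parsed command-line flags) take precedence
#' over the file.
#'
#' @param file path to the config file (or `NULL` for overrides only).
#' @param overrides named list of values overriding the file.
#' @return A named list.
#' @export
read_run_config <- function(file = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(file)) {
    lines <- readLines(file)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl(":", lines)])
    for (l in lines[nzchar(lines)]) {
      key <- trimws(sub(":.*$", "", l))
      val <- trimws(sub("^[^:]*:", "", l))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  utils::modifyList(cfg, overrides)
}
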