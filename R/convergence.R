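#' Second-level convergence test between miRNA sets
#'
#' Tests whether the miRNAs that share a common target (e.g. the REST mRNA)
#' are enriched within a disorder-associated miRNA set, by the upper-tail
#' central hypergeometric probability over the miRNA universe: with
#' `M = |universe|`, `D = |disorder set|`, `R = |shared-target set|` and
#' `x = |overlap|`, `p = P(X >= x)` for `Hypergeometric(N = M, K = D,
#' n = R)`. The universe defaults to the upregulated survivor set, the
#' population the disorder and shared-target sets were drawn from.
#'
#' @param universe [gene_set] of all miRNAs under consideration.
#' @param disorder_set [gene_set] of disorder-associated miRNAs (subset of
#'   the universe).
#' @param rest_set [gene_set] of shared-target (e.g. REST-targeting) miRNAs
#'   (subset of the universe).
#' @param alpha significance bound (default 0.05).
#' @return A one-row data.frame of class `convergence_result`: `disorder`,
#'   `M`, `D`, `R`, `x`, `p_value`, `significant`.
#' @examples
#' u <- gene_set("up", paste0("m", 1:56))
#' d <- gene_set("ID", paste0("m", 1:43))
#' r <- gene_set("REST", paste0("m", 1:11))
#' convergence_test(u, d, r)  # p ~ 0.0386, significant
#' @export
convergence_test <- function(universe, disorder_set, rest_set,
                             alpha = 0.05) {
  stopifnot(inherits(universe, "gene_set"),
            inherits(disorder_set, "gene_set"),
            inherits(rest_set, "gene_set"))
  bad_d <- setdiff(disorder_set$genes, universe$genes)
  bad_r <- setdiff(rest_set$genes, universe$genes)
  if (length(bad_d) || length(bad_r))
    stop("ids outside the universe: ",
         paste(c(bad_d, bad_r), collapse = ", "))
  M <- length(universe); D <- length(disorder_set); R <- length(rest_set)
  x <- length(intersect(disorder_set$genes, rest_set$genes))
  p <- hypergeom_sf(M, D, R, x)
  out <- data.frame(disorder = disorder_set$name, M = M, D = D, R = R,
                    x = x, p_value = p, significant = p < alpha)
  class(out) <- c("convergence_result", "data.frame")
  out
}

#' @export
print.convergence_result <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "%s: %d of %d shared-target miRNAs in a %d-member set (universe %d), p = %.4g%s\n",
      x$disorder[i], x$x[i], x$R[i], x$D[i], x$M[i], x$p_value[i],
      if (x$significant[i]) " *" else ""))
  invisible(x)
}

#' Three-set Venn decomposition of miRNA memberships
#'
#' Partitions a miRNA collection into the 7 regions of the three disorder
#' sets (plus the outside region), and extracts the core set: the members of
#' the triple intersection. Region counts always sum to the collection size.
#'
#' @param sets named list of exactly three [gene_set]s (e.g. ID, SCZ, ASD),
#'   each a subset of `collection`.
#' @param collection [gene_set] over which to decompose (e.g. the
#'   REST-targeting miRNAs).
#' @return An object of class `venn_summary`: `counts` (named vector over
#'   the 8 regions), `regions` (ids per region) and `core` ([gene_set] of
#'   the triple intersection).
#' @export
venn_decompose <- function(sets, collection) {
  stopifnot(length(sets) == 3L, inherits(collection, "gene_set"))
  nm <- vapply(sets, function(s) s$name, character(1))
  for (s in sets) {
    bad <- setdiff(s$genes, collection$genes)
    if (length(bad)) stop("ids outside collection: ",
                          paste(bad, collapse = ", "))
  }
  mem <- vapply(sets, function(s) collection$genes %in% s$genes,
                logical(length(collection$genes)))
  if (length(collection$genes) == 1L) mem <- matrix(mem, nrow = 1)
  key <- apply(mem, 1, function(b) {
    lab <- paste(nm[b], collapse = "&")
    if (lab == "") "none" else lab
  })
  all_regions <- c(nm, paste(nm[1], nm[2], sep = "&"),
                   paste(nm[1], nm[3], sep = "&"),
                   paste(nm[2], nm[3], sep = "&"),
                   paste(nm, collapse = "&"), "none")
  regions <- lapply(all_regions, function(r) collection$genes[key == r])
  names(regions) <- all_regions
  counts <- lengths(regions)
  core <- gene_set(paste0("core_", paste(nm, collapse = "_")),
                   regions[[paste(nm, collapse = "&")]])
  structure(list(counts = counts, regions = regions, core = core,
                 set_names = nm, collection = collection$name),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Venn decomposition of '", x$collection, "' over ",
      paste(x$set_names, collapse = "/"), ":\n", sep = "")
  for (r in names(x$counts)) cat(sprintf("  %-20s %d\n", r, x$counts[[r]]))
  cat("core set (", length(x$core), "): ",
      paste(x$core$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Core set of a Venn decomposition
#'
#' @param venn a `venn_summary`.
#' @return The triple-intersection [gene_set], members sorted.
#' @export
core_set <- function(venn) {
  stopifnot(inherits(venn, "venn_summary"))
  gene_set(venn$core$name, sort(venn$core$genes))
}

#' @export
plot.venn_summary <- function(x, ...) {
  # basic three-circle Venn with region counts
  ang <- c(90, 210, 330) * pi / 180
  cx <- 0.35 * cos(ang); cy <- 0.35 * sin(ang)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in 1:3)
    graphics::lines(cx[i] + 0.62 * cos(th), cy[i] + 0.62 * sin(th))
  graphics::text(1.55 * cx, 1.55 * cy, x$set_names)
  nm <- x$set_names
  pos <- rbind(c(0, 0.55), c(-0.5, -0.3), c(0.5, -0.3),      # singles
               c(-0.28, 0.18), c(0.28, 0.18), c(0, -0.38),   # pairs
               c(0, 0))                                      # triple
  lab <- c(nm, paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
           paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&"))
  graphics::text(pos[, 1], pos[, 2], x$counts[lab])
  invisible(x)
}
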