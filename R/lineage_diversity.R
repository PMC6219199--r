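# lineage_diversity: per-region lineage richness through time and the
# weighted-mean lineage diversity at internal nodes.
#
# Conventions (exposed as switches, echoed in output metadata):
#   include_origin: the stem lineage above the root counts once, attributed
#     by the root's probability vector, so that summed richness equals the
#     exact lineage-through-time count at every age.
#   strict_older: "earlier" means strictly greater age than the focal time;
#     the focal node's own divergence is excluded, and the curve is
#     right-continuous in age.
#   threshold (0.70): nodes whose maximum single-region probability falls
#     below it are flagged unprocessed; they keep their row (diversity
#     blank in tables) but still contribute to every richness sum --
#     dropping them would undercount lineages.

# internal-node probability rows, with per-node error reporting
.internal_probs <- function(tt, probs) {
  n <- tt$n_tip
  M <- n + tt$phy$Nnode
  .assert(is.matrix(probs) && nrow(probs) == M,
          "probability matrix must have one row per node (%d)", M)
  internal <- (n + 1L):M
  miss <- internal[!stats::complete.cases(probs[internal, , drop = FALSE])]
  if (length(miss))
    stop(sprintf("internal node %d has no probability vector", miss[1]),
         call. = FALSE)
  probs
}

#' Number of lineages at a given age
#'
#' Counts the origin lineage plus one lineage per divergence event strictly
#' older than `t` (a node with `d` children contributes `d - 1` events).
#'
#' @param tree a `time_tree` (or coercible).
#' @param t age in My.
#' @param strict_older if `TRUE` (default) only strictly older divergences
#'   count.
#' @return integer lineage count (1 at or above the root age, number of
#'   tips at age 0).
#' @export
lineage_count <- function(tree, t, strict_older = TRUE) {
  tt <- .coerce_tree(tree)
  n <- tt$n_tip
  internal <- (n + 1L):(n + tt$phy$Nnode)
  contrib <- .n_children(tt$phy)[internal] - 1L
  keep <- if (strict_older) tt$ages[internal] > t else tt$ages[internal] >= t
  1L + sum(contrib[keep])
}

#' Per-region lineage richness at an age
#'
#' The expected number of lineages attributable to each region at age `t`:
#' the sum of location-probability vectors over all divergences older than
#' `t`, plus (by default) the root's vector once for the origin lineage.
#' With that origin term the regional values always sum to the exact
#' lineage-through-time count.
#'
#' @param tree a `time_tree` (or coercible).
#' @param probs a `state_posterior` matrix (nodes x regions); every internal
#'   node must have a vector.
#' @param t age in My, `t >= 0`.
#' @param include_origin count the stem lineage above the root (default
#'   `TRUE`).
#' @param strict_older see [lineage_count()].
#' @return named numeric vector over regions.
#' @export
regional_richness <- function(tree, probs, t, include_origin = TRUE,
                              strict_older = TRUE) {
  tt <- .coerce_tree(tree)
  .assert(is.numeric(t) && length(t) == 1L && t >= 0, "age t must be >= 0")
  probs <- .internal_probs(tt, probs)
  n <- tt$n_tip
  internal <- (n + 1L):(n + tt$phy$Nnode)
  contrib <- .n_children(tt$phy)[internal] - 1L
  keep <- if (strict_older) tt$ages[internal] > t else tt$ages[internal] >= t
  w <- contrib * keep
  rich <- as.vector(t(probs[internal, , drop = FALSE]) %*% w)
  if (include_origin) rich <- rich + probs[tt$root, ]
  stats::setNames(rich, colnames(probs))
}

#' Lineage diversity at a focal internal node
#'
#' The element-wise product of the regional richness vector at the focal
#' node's age (older divergences only) with the focal node's own location
#' probabilities, summed: the weighted mean of the regional lineage
#' diversities the node could have belonged to.  Nodes whose maximum
#' location probability is below `threshold` are flagged `processed =
#' FALSE`; the value is still computed so that either reporting convention
#' can be applied downstream.
#'
#' @inheritParams regional_richness
#' @param focal internal node id.
#' @param threshold minimum maximum-probability for a node to be processed
#'   (default 0.70).
#' @return list with `node`, `age`, `probs`, `richness`, `diversity`,
#'   `processed`.
#' @export
node_diversity <- function(tree, probs, focal, threshold = 0.70,
                           include_origin = TRUE, strict_older = TRUE) {
  tt <- .coerce_tree(tree)
  probs <- .internal_probs(tt, probs)
  focal <- as.integer(focal)
  .assert(focal > tt$n_tip && focal <= nrow(probs),
          "focal node %d is a tip or out of range", focal)
  p <- probs[focal, ]
  rich <- regional_richness(tt, probs, t = tt$ages[focal],
                            include_origin = include_origin,
                            strict_older = strict_older)
  list(node = focal, age = tt$ages[focal], probs = p, richness = rich,
       diversity = sum(p * rich), processed = max(p) >= threshold)
}

#' Diversity table over all internal nodes
#'
#' One record per internal node, ordered oldest first.  Ages, credible
#' intervals and support are copied from node annotations when present
#' (keys configurable; BEAST defaults) and otherwise taken from the tree /
#' left `NA`.  Computation always uses the tree's own point-estimate ages.
#'
#' @inheritParams node_diversity
#' @param annotations node annotations (default: the tree's own).
#' @param age_keys annotation keys tried, in order, for mean age and CI.
#' @param support_key annotation key for node support.
#' @return data frame with columns `node`, `age_mean`, `age_lower`,
#'   `age_upper`, `support`, one probability column per region,
#'   `lineage_diversity`, `processed`; attributes `regions` and
#'   `conventions` record the settings used.
#' @export
diversity_table <- function(tree, probs, threshold = 0.70,
                            include_origin = TRUE, strict_older = TRUE,
                            annotations = NULL,
                            age_keys = c("height", "height_median"),
                            support_key = "posterior") {
  tt <- .coerce_tree(tree)
  probs <- .internal_probs(tt, probs)
  if (is.null(annotations)) annotations <- tt$annotations
  n <- tt$n_tip
  internal <- (n + 1L):(n + tt$phy$Nnode)
  contrib <- .n_children(tt$phy)[internal] - 1L
  ages <- tt$ages[internal]
  P <- probs[internal, , drop = FALSE]

  res <- .diversity_core(ages, P, contrib,
                         origin = if (include_origin) probs[tt$root, ] else NULL,
                         strict_older = strict_older)

  support <- age_lower <- age_upper <- rep(NA_real_, length(internal))
  age_mean <- ages
  age_key_used <- NA_character_
  if (!is.null(annotations)) {
    for (i in seq_along(internal)) {
      a <- annotations[[as.character(internal[i])]]
      if (is.null(a)) next
      for (k in age_keys) if (!is.null(a[[k]])) {
        age_mean[i] <- a[[k]][1]
        age_key_used <- k
        break
      }
      hpd <- a[["height_95%_HPD"]]
      if (is.null(hpd)) hpd <- a[["age_CI"]]
      if (!is.null(hpd) && length(hpd) == 2) {
        age_lower[i] <- min(hpd); age_upper[i] <- max(hpd)
      }
      if (!is.null(a[[support_key]])) support[i] <- a[[support_key]][1]
    }
  }

  out <- data.frame(node = internal, age_mean = age_mean,
                    age_lower = age_lower, age_upper = age_upper,
                    support = support, check.names = FALSE)
  for (j in seq_len(ncol(P))) out[[colnames(P)[j]]] <- P[, j]
  out$lineage_diversity <- res$diversity
  out$processed <- apply(P, 1, max) >= threshold
  out <- out[order(out$age_mean, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regions") <- colnames(P)
  attr(out, "conventions") <- list(include_origin = include_origin,
                                   strict_older = strict_older,
                                   threshold = threshold,
                                   age_column = age_key_used)
  out
}

# shared richness/diversity arithmetic on (ages, prob rows, event weights).
# Returns per-row diversity and a function evaluating richness at any age.
.diversity_core <- function(ages, P, contrib, origin, strict_older) {
  ord <- order(ages, decreasing = TRUE)
  Ps <- P[ord, , drop = FALSE] * contrib[ord]
  as_ <- ages[ord]
  cum <- apply(Ps, 2, cumsum)
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1)
  origin_v <- if (is.null(origin)) rep(0, ncol(P)) else origin
  rich_at <- function(t) {
    k <- if (strict_older) sum(as_ > t) else sum(as_ >= t)
    v <- if (k > 0) cum[k, ] else rep(0, ncol(P))
    stats::setNames(v + origin_v, colnames(P))
  }
  # strictly-older counts for the node rows themselves (ties share a value)
  k_each <- vapply(ages, function(a)
    if (strict_older) sum(as_ > a) else sum(as_ >= a), integer(1))
  rich_rows <- t(vapply(k_each, function(k)
    (if (k > 0) cum[k, ] else rep(0, ncol(P))) + origin_v,
    numeric(ncol(P))))
  list(diversity = rowSums(P * rich_rows), rich_at = rich_at,
       richness_rows = rich_rows)
}

#' Diversity from a bare node table (no tree required)
#'
#' Under the strictly-older convention on a binary tree, richness and node
#' diversity depend only on the node ages and probability vectors, not on
#' the topology.  This computes the diversity column directly from a table
#' such as a published divergence-time / ancestral-state summary.  The
#' oldest row is taken as the root for the origin-lineage term.
#'
#' @param node_table data frame with columns `node`, `age` (or `age_mean`),
#'   one column per region, and optionally `age_lower`, `age_upper`,
#'   `support`.
#' @param regions region labels; default [default_regions()].
#' @inheritParams node_diversity
#' @return data frame in the same schema as [diversity_table()].
#' @export
diversity_from_node_table <- function(node_table, regions = default_regions(),
                                      threshold = 0.70, include_origin = TRUE,
                                      strict_older = TRUE) {
  regions <- as_region_set(regions)
  age_col <- intersect(c("age", "age_mean"), names(node_table))[1]
  .assert(!is.na(age_col), "node_table needs an 'age' or 'age_mean' column")
  .assert(all(unname(regions) %in% names(node_table)),
          "node_table lacks a column for each region")
  ages <- as.numeric(node_table[[age_col]])
  P <- as.matrix(node_table[, unname(regions), drop = FALSE])
  P <- t(apply(P, 1, .normalize_prob, what = "node-table row"))
  colnames(P) <- unname(regions)
  contrib <- rep(1L, nrow(P))
  root_row <- which.max(ages)
  res <- .diversity_core(ages, P, contrib,
                         origin = if (include_origin) P[root_row, ] else NULL,
                         strict_older = strict_older)
  out <- data.frame(
    node = if ("node" %in% names(node_table)) node_table$node else seq_len(nrow(P)),
    age_mean = ages,
    age_lower = if ("age_lower" %in% names(node_table))
      node_table$age_lower else NA_real_,
    age_upper = if ("age_upper" %in% names(node_table))
      node_table$age_upper else NA_real_,
    support = if ("support" %in% names(node_table))
      node_table$support else NA_real_,
    check.names = FALSE)
  for (j in seq_len(ncol(P))) out[[colnames(P)[j]]] <- P[, j]
  out$lineage_diversity <- res$diversity
  out$processed <- apply(P, 1, max) >= threshold
  out <- out[order(out$age_mean, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regions") <- colnames(P)
  attr(out, "conventions") <- list(include_origin = include_origin,
                                   strict_older = strict_older,
                                   threshold = threshold,
                                   age_column = age_col)
  out
}

#' Richness curves on an age grid, plus per-node plot payload
#'
#' Evaluates the per-region richness step function on a grid of ages
#' (right-continuous under the strictly-older convention: a grid point
#' exactly at a node age takes its value from the strictly older set) and
#' returns, alongside, the per-node (age, diversity, probabilities) triples
#' used for diversity-versus-time plots, with a flag marking nodes whose
#' highest-probability region is the focal one (default the Japanese
#' Archipelago, region `IV`).
#'
#' @inheritParams diversity_table
#' @param grid numeric vector of ages (My), each `>= 0`.
#' @param flag_region region label to flag in the node payload.
#' @return list with `grid` (long data frame: `age`, `region`, `richness`)
#'   and `nodes` (data frame: `node`, `age`, region probabilities,
#'   `lineage_diversity`, `processed`, `flagged`).
#' @export
richness_through_time <- function(tree, probs, grid, threshold = 0.70,
                                  include_origin = TRUE, strict_older = TRUE,
                                  flag_region = NULL) {
  tt <- .coerce_tree(tree)
  probs <- .internal_probs(tt, probs)
  .assert(is.numeric(grid) && all(grid >= 0), "grid ages must be >= 0")
  regions <- colnames(probs)
  if (is.null(flag_region)) flag_region <- regions[length(regions)]
  .assert(flag_region %in% regions, "flag_region '%s' not in the region set",
          flag_region)
  n <- tt$n_tip
  internal <- (n + 1L):(n + tt$phy$Nnode)
  contrib <- .n_children(tt$phy)[internal] - 1L
  res <- .diversity_core(tt$ages[internal], probs[internal, , drop = FALSE],
                         contrib,
                         origin = if (include_origin) probs[tt$root, ] else NULL,
                         strict_older = strict_older)
  if (length(grid)) {
    vals <- t(vapply(grid, res$rich_at, numeric(length(regions))))
    long <- data.frame(age = rep(grid, times = length(regions)),
                       region = rep(regions, each = length(grid)),
                       richness = as.vector(vals))
  } else {
    long <- data.frame(age = numeric(0), region = character(0),
                       richness = numeric(0))
  }
  P <- probs[internal, , drop = FALSE]
  nodes <- data.frame(node = internal, age = tt$ages[internal],
                      check.names = FALSE)
  for (j in seq_along(regions)) nodes[[regions[j]]] <- P[, j]
  nodes$lineage_diversity <- res$diversity
  nodes$processed <- apply(P, 1, max) >= threshold
  nodes$flagged <- regions[max.col(P, ties.method = "first")] == flag_region
  nodes <- nodes[order(nodes$age, decreasing = TRUE), , drop = FALSE]
  rownames(nodes) <- NULL
  attr(long, "conventions") <- attr(nodes, "conventions") <-
    list(include_origin = include_origin, strict_older = strict_older,
         threshold = threshold, flag_region = flag_region)
  list(grid = long, nodes = nodes)
}

#' Minimal diversity-versus-time plot (decoration)
#'
#' Base-graphics sketch of the node payload from
#' [richness_through_time()]: diversity against age, flagged nodes
#' highlighted, with an optional vertical reference line (e.g. 1.7 Ma, the
#' cleavage of the southern Japan Sea strait).
#'
#' @param nodes the `nodes` element of [richness_through_time()].
#' @param reference_age optional vertical line position (Ma).
#' @param ... passed to [plot()].
#' @return invisibly, `nodes`.
#' @export
plot_node_diversity <- function(nodes, reference_age = NULL, ...) {
  keep <- nodes$processed
  plot(nodes$age[keep], nodes$lineage_diversity[keep],
       xlim = rev(range(nodes$age)), xlab = "Age (Ma)",
       ylab = "Lineage diversity", pch = 21,
       bg = ifelse(nodes$flagged[keep], "pink", "grey"), ...)
  if (!is.null(reference_age))
    graphics::abline(v = reference_age, lty = 3, col = "pink3")
  invisible(nodes)
}
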