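# asr: discrete-region ancestral state reconstruction on a fixed time tree.
#
# A continuous-time Markov chain over K regions runs along branches; the
# pruning algorithm gives the likelihood and an inside-outside pass gives
# marginal node probabilities.  These are point-estimate (empirical Bayes)
# marginals on a FIXED tree -- not a joint Bayesian tree+state posterior.
# When externally produced probabilities exist (e.g. from an MCC tree), feed
# them straight into the lineage_diversity stage instead.

#' Default biogeographic region set
#'
#' Four regions coded `I` to `IV`: Palearctic, Oriental, Nearctic, and the
#' Japanese Archipelago.  The order of the labels fixes the axis of every
#' probability and richness vector in the package.
#'
#' @return character vector of labels, with display names as names.
#' @export
default_regions <- function() {
  c(Palearctic = "I", Oriental = "II", Nearctic = "III",
    `Japanese Archipelago` = "IV")
}

#' Validate a region set
#' @param regions character vector of unique labels, length >= 2.
#' @return the region set (names preserved if present).
#' @export
as_region_set <- function(regions) {
  .assert(is.character(regions) && length(regions) >= 2,
          "a region set needs at least two character labels")
  .assert(!anyDuplicated(regions), "region labels must be unique")
  regions
}

#' Construct a dispersal CTMC model
#'
#' @param regions region labels (axis of the rate matrix).
#' @param rate single rate for the equal-rates symmetric structure (`"ER"`):
#'   every off-diagonal of Q equals `rate`.
#' @param rates rate vector for `"SYM"` (upper triangle, by column) or
#'   `"ARD"` (off-diagonals, by column).
#' @param Q full rate matrix (overrides `rate`/`rates`); off-diagonals must
#'   be non-negative, rows must sum to zero.
#' @param prior root prior over regions; default the stationary distribution
#'   of Q (uniform for symmetric structures), the standard neutral choice
#'   since the generating process is assumed at equilibrium at the origin.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @return object of class `ctmc_model` with elements `Q`, `prior`,
#'   `regions`, `structure`, `rate` (ER only).
#' @export
ctmc_model <- function(regions = default_regions(), rate = NULL, rates = NULL,
                       Q = NULL, prior = NULL,
                       structure = c("ER", "SYM", "ARD")) {
  structure <- match.arg(structure)
  regions <- as_region_set(regions)
  K <- length(regions)
  if (is.null(Q)) {
    if (structure == "ER") {
      .assert(is.numeric(rate) && length(rate) == 1L && rate >= 0,
              "ER structure needs a single non-negative 'rate'")
      Q <- matrix(rate, K, K)
    } else {
      npar <- if (structure == "SYM") K * (K - 1) / 2 else K * (K - 1)
      .assert(length(rates) == npar && all(rates >= 0),
              "%s structure needs %d non-negative rates", structure, npar)
      Q <- matrix(0, K, K)
      if (structure == "SYM") {
        Q[upper.tri(Q)] <- rates
        Q <- Q + t(Q)
      } else {
        Q[row(Q) != col(Q)] <- rates
      }
    }
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
  } else {
    .assert(is.matrix(Q) && nrow(Q) == K && ncol(Q) == K,
            "Q must be %d x %d", K, K)
    .assert(all(Q[row(Q) != col(Q)] >= 0), "off-diagonal rates must be >= 0")
    .assert(max(abs(rowSums(Q))) < 1e-12, "rows of Q must sum to 0")
    rate <- NULL
  }
  if (is.null(prior)) prior <- stationary_distribution(Q)
  .assert(length(prior) == K && all(prior >= 0) &&
            abs(sum(prior) - 1) < 1e-12,
          "root prior must be a probability vector over the regions")
  dimnames(Q) <- list(unname(regions), unname(regions))
  obj <- list(Q = Q, prior = unname(prior), regions = regions,
              structure = structure,
              rate = if (structure == "ER") rate else NULL)
  class(obj) <- "ctmc_model"
  obj
}

#' Stationary distribution of a rate matrix
#'
#' Solves pi Q = 0 with pi summing to 1 (left null vector of Q).
#'
#' @param Q square rate matrix with zero row sums.
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(Q) {
  K <- nrow(Q)
  if (max(abs(Q)) == 0) return(rep(1 / K, K))
  Q <- Q / max(abs(Q))  # scale-free: conditions the solve for tiny rates
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

#' Transition probability matrix P(t) = exp(Q t)
#'
#' Equal-rates symmetric chains use the exact closed form
#' `P(same) = 1/K + (K-1)/K * exp(-K q t)`; other structures use the matrix
#' exponential.  The result is checked to be row-stochastic to 1e-9.
#'
#' @param model a `ctmc_model`.
#' @param t branch duration in My, `t >= 0`.
#' @return K x K row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  .assert(inherits(model, "ctmc_model"), "need a ctmc_model")
  .assert(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0,
          "duration t must be a finite non-negative number")
  K <- nrow(model$Q)
  if (identical(model$structure, "ER") && !is.null(model$rate)) {
    e <- exp(-K * model$rate * t)
    P <- matrix((1 - e) / K, K, K)
    diag(P) <- 1 / K + (K - 1) / K * e
  } else {
    P <- as.matrix(Matrix::expm(model$Q * t))
    P[P < 0] <- 0
  }
  .assert(max(abs(rowSums(P) - 1)) < 1e-9,
          "matrix exponential lost row-stochasticity (max dev %.3g)",
          max(abs(rowSums(P) - 1)))
  dimnames(P) <- dimnames(model$Q)
  P
}

# tip states -> n x K probability matrix.  Accepts a named character vector
# of region labels (NA = missing), or a matrix with rownames = tip labels.
# Missing / ambiguous tips get an all-ones vector (standard missing data).
.tip_prob_matrix <- function(tt, tip_states, regions) {
  n <- tt$n_tip
  K <- length(regions)
  tipP <- matrix(1, n, K)
  if (is.matrix(tip_states) || is.data.frame(tip_states)) {
    tip_states <- as.matrix(tip_states)
    hit <- match(tt$phy$tip.label, rownames(tip_states))
    .assert(!anyNA(hit), "tip '%s' has no state vector",
            tt$phy$tip.label[which(is.na(hit))[1]])
    tipP <- tip_states[hit, , drop = FALSE]
    .assert(ncol(tipP) == K, "tip state matrix must have %d columns", K)
  } else {
    .assert(!is.null(names(tip_states)), "tip states must be named by tip label")
    hit <- match(tt$phy$tip.label, names(tip_states))
    .assert(!anyNA(hit), "tip '%s' has no state",
            tt$phy$tip.label[which(is.na(hit))[1]])
    st <- unname(tip_states[hit])
    for (i in seq_len(n)) {
      if (is.na(st[i])) next  # ambiguous: all ones
      j <- match(st[i], unname(regions))
      .assert(!is.na(j), "tip '%s' has region '%s' outside the region set",
              tt$phy$tip.label[i], st[i])
      tipP[i, ] <- 0
      tipP[i, j] <- 1
    }
  }
  rownames(tipP) <- tt$phy$tip.label
  tipP
}

# shared pruning machinery: per-edge transition matrices and scaled inside
# partials.  Returns list(phy_po, L, logscale, Plist_index) where L[v, ] are
# the inside partials of node v scaled to max 1 and logscale[v] the dropped
# log factor.
.prune <- function(tt, tipP, model) {
  phy <- tt$phy
  n <- tt$n_tip
  M <- n + phy$Nnode
  K <- ncol(tipP)
  po <- ape::reorder.phylo(phy, "postorder")
  Pmats <- lapply(po$edge.length, function(len) transition_probabilities(model, len))
  L <- matrix(1, M, K)
  L[seq_len(n), ] <- tipP
  logscale <- numeric(M)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    lc <- L[ch, ]
    sc <- max(lc)
    .assert(sc > 0, "zero partial likelihood below node %d", ch)
    logscale[ch] <- logscale[ch] + log(sc)
    L[p, ] <- L[p, ] * as.vector(Pmats[[e]] %*% (lc / sc))
    logscale[p] <- logscale[p] + logscale[ch]
  }
  list(po = po, L = L, logscale = logscale, Pmats = Pmats)
}

#' Log-likelihood of tip regions under a dispersal CTMC
#'
#' Felsenstein pruning on the fixed time tree:
#' `log sum_s prior_s * L_root(s)`, with per-node scaling for numerical
#' stability.
#'
#' @param tree a `time_tree` (or coercible).
#' @param tip_states named character vector (tip label -> region label;
#'   `NA` = unsampled, treated as missing data) or a tip-by-region
#'   probability matrix with tip labels as rownames.
#' @param model a `ctmc_model`.
#' @return log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, tip_states, model) {
  tt <- .coerce_tree(tree)
  tipP <- .tip_prob_matrix(tt, tip_states, model$regions)
  pr <- .prune(tt, tipP, model)
  r <- tt$root
  log(sum(model$prior * pr$L[r, ])) + pr$logscale[r]
}

#' Marginal ancestral region probabilities at every node
#'
#' Inside-outside algorithm: for each internal node the marginal probability
#' of each region given all tip states is the product of inside and outside
#' partial likelihoods, normalized.  Tips return their own (one-hot or
#' ambiguity) vectors.
#'
#' @inheritParams tree_log_likelihood
#' @return a `state_posterior` matrix (nodes x regions), each row summing
#'   to 1.
#' @export
marginal_node_probabilities <- function(tree, tip_states, model) {
  tt <- .coerce_tree(tree)
  regions <- model$regions
  K <- length(regions)
  tipP <- .tip_prob_matrix(tt, tip_states, regions)
  pr <- .prune(tt, tipP, model)
  phy <- tt$phy
  n <- tt$n_tip
  M <- n + phy$Nnode

  # outside pass in cladewise (parent-before-child) edge order
  cw <- ape::reorder.phylo(phy, "cladewise")
  U <- matrix(NA_real_, M, K)
  U[tt$root, ] <- model$prior
  # index edges by parent, preserving cladewise order of parents
  eo <- seq_len(nrow(cw$edge))
  by_parent <- split(eo, cw$edge[, 1])
  parent_order <- unique(cw$edge[, 1])
  Pcw <- lapply(cw$edge.length, function(len) transition_probabilities(model, len))
  for (v in parent_order) {
    edges <- by_parent[[as.character(v)]]
    Svals <- lapply(edges, function(e)
      as.vector(Pcw[[e]] %*% pr$L[cw$edge[e, 2], ]))
    Sall <- do.call(cbind, Svals)  # K x nchild, entries S_j(s_v)
    for (j in seq_along(edges)) {
      e <- edges[j]
      ch <- cw$edge[e, 2]
      others <- Sall[, -j, drop = FALSE]
      prod_others <- apply(others, 1, prod)
      w <- U[v, ] * prod_others
      u <- as.vector(t(Pcw[[e]]) %*% w)
      s <- sum(u)
      U[ch, ] <- if (s > 0) u / s else rep(1 / K, K)
    }
  }

  post <- matrix(NA_real_, M, K)
  post[seq_len(n), ] <- tipP
  for (v in (n + 1L):M) {
    m <- pr$L[v, ] * U[v, ]
    post[v, ] <- m / sum(m)
  }
  .new_state_posterior(post, regions)
}

#' Maximum-likelihood dispersal rate on a fixed tree
#'
#' For the equal-rates structure, a deterministic 1-D bounded maximization
#' of [tree_log_likelihood()] over `q` in `[lower, q_max]` (tolerance 1e-8).
#' Free structures use L-BFGS-B on log rates from a fixed fan of starting
#' points (deterministic, no random restarts).  Data with a single observed
#' region cannot identify a rate: the lower bound is returned with a warning
#' and `status = "not_identifiable"`.
#'
#' @inheritParams tree_log_likelihood
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param lower,q_max search bounds on each rate; `q_max` defaults to
#'   `1000 / root age`, deep inside the ergodic-limit plateau.
#' @param regions region labels.
#' @return a `ctmc_model` with extra elements `log_lik`, `status`
#'   (`"converged"`, `"boundary"` or `"not_identifiable"`).
#' @export
fit_rate <- function(tree, tip_states, structure = c("ER", "SYM", "ARD"),
                     regions = default_regions(), lower = 1e-8, q_max = NULL,
                     prior = NULL) {
  structure <- match.arg(structure)
  tt <- .coerce_tree(tree)
  regions <- as_region_set(regions)
  K <- length(regions)
  if (is.null(q_max)) q_max <- 1000 / max(tt$ages)
  tipP <- .tip_prob_matrix(tt, tip_states, regions)

  observed <- apply(tipP, 1, function(p) {
    hits <- which(p > 0)
    if (length(hits) == 1L) hits else NA_integer_
  })
  if (length(unique(stats::na.omit(observed))) < 2L) {
    warning("rate not identifiable: all observed tips share one region; ",
            "lower bound returned")
    m <- ctmc_model(regions, rate = lower, prior = prior, structure = "ER")
    m$log_lik <- tree_log_likelihood(tt, tipP, m)
    m$status <- "not_identifiable"
    return(m)
  }

  if (structure == "ER") {
    f <- function(q) tree_log_likelihood(
      tt, tipP, ctmc_model(regions, rate = q, prior = prior, structure = "ER"))
    opt <- stats::optimize(f, c(lower, q_max), maximum = TRUE, tol = 1e-8)
    q_hat <- opt$maximum
    m <- ctmc_model(regions, rate = q_hat, prior = prior, structure = "ER")
    m$log_lik <- opt$objective
    m$status <- if (q_hat < lower * 2 || q_hat > q_max * 0.99) "boundary"
                else "converged"
    return(m)
  }

  npar <- if (structure == "SYM") K * (K - 1) / 2 else K * (K - 1)
  nll <- function(lr) -tree_log_likelihood(
    tt, tipP, ctmc_model(regions, rates = exp(lr), prior = prior,
                         structure = structure))
  starts <- lapply(c(0.01, 0.1, 1) / max(tt$ages), function(s) rep(log(s), npar))
  fits <- lapply(starts, function(s)
    stats::optim(s, nll, method = "L-BFGS-B",
                 lower = log(lower), upper = log(q_max),
                 control = list(factr = 1e4)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  m <- ctmc_model(regions, rates = exp(best$par), prior = prior,
                  structure = structure)
  m$log_lik <- -best$value
  m$status <- if (best$convergence == 0) "converged" else "boundary"
  m
}
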