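# fixtures and independent oracles built in code

TOY_NEWICK <- "((A:1,B:1):2,(C:2,D:2):1);"

toy_tree <- function() read_time_tree(text = TOY_NEWICK)

# node ids in the toy tree (ape numbering): tips A..D = 1..4,
# root = 5 (age 3), AB = 6 (age 1), CD = 7 (age 2)
toy_probs <- function() {
  pm <- matrix(NA_real_, 7, 2)
  pm[5, ] <- c(0.7, 0.3)  # root
  pm[6, ] <- c(0.1, 0.9)  # AB, age 1
  pm[7, ] <- c(0.6, 0.4)  # CD, age 2
  regiodiv:::.new_state_posterior(pm, c("I", "IV"))
}

toy_onehot <- function(root = "I", ab = "IV", cd = "I") {
  oh <- function(r) if (r == "I") c(1, 0) else c(0, 1)
  pm <- matrix(NA_real_, 7, 2)
  pm[5, ] <- oh(root); pm[6, ] <- oh(ab); pm[7, ] <- oh(cd)
  regiodiv:::.new_state_posterior(pm, c("I", "IV"))
}

# random ultrametric tree from a different generator than simulate_yule
random_ultrametric <- function(n) as_time_tree(ape::rcoal(n))

random_ctmc <- function(K, regions = paste0("R", seq_len(K))) {
  Q <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  prior <- stats::runif(K); prior <- prior / sum(prior)
  ctmc_model(regions, Q = Q, prior = prior)
}

# independent transition matrix: matrix exponential straight from Matrix
expm_direct <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# exhaustive-enumeration likelihood and marginals over internal-node states,
# independent of the pruning implementation
enum_asr <- function(tt, tipP, model) {
  phy <- tt$phy
  n <- tt$n_tip
  M <- n + phy$Nnode
  K <- nrow(model$Q)
  internal <- (n + 1L):M
  Pm <- lapply(seq_len(nrow(phy$edge)),
               function(e) expm_direct(model$Q, phy$edge.length[e]))
  A <- as.matrix(expand.grid(rep(list(seq_len(K)), length(internal))))
  node_col <- function(v) A[, match(v, internal)]
  w <- model$prior[node_col(tt$root)]
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (ch <= n) {
      # tip edge: sum over tip states weighted by the tip vector
      tipw <- as.vector(Pm[[e]] %*% tipP[ch, ])
      w <- w * tipw[node_col(p)]
    } else {
      w <- w * Pm[[e]][cbind(node_col(p), node_col(ch))]
    }
  }
  lik <- sum(w)
  marg <- matrix(NA_real_, M, K)
  for (v in internal) for (k in seq_len(K))
    marg[v, k] <- sum(w[node_col(v) == k]) / lik
  list(log_lik = log(lik), marginals = marg)
}

# lineage count by branch-crossing, independent of lineage_count()
ltt_crossing <- function(tt, t) {
  ages <- tt$ages
  if (t >= ages[tt$root]) return(1L)
  e <- tt$phy$edge
  sum(ages[e[, 1]] > t & ages[e[, 2]] <= t)
}

# random normalized probability rows for every internal node
random_posterior <- function(tt, K = 4, regions = paste0("R", seq_len(K))) {
  M <- tt$n_tip + tt$phy$Nnode
  pm <- matrix(NA_real_, M, K)
  for (v in (tt$n_tip + 1L):M) {
    p <- stats::runif(K)
    pm[v, ] <- p / sum(p)
  }
  regiodiv:::.new_state_posterior(pm, regions)
}

published_node_table <- function() {
  path <- system.file("extdata", "planorbid_node_table.tsv",
                      package = "regiodiv")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
}
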