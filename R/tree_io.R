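# tree_io: reading, validating and writing time trees and node annotations.
#
# Trees are ape "phylo" objects wrapped in a light "time_tree" structure that
# adds node ages (My, measured backward from the tips), an ultrametricity
# tolerance, and any node annotations recovered from bracketed comments.
# Node ids follow ape numbering: tips 1..n, internal nodes n+1..n+Nnode with
# the root at n+1 for freshly parsed trees.

#' Construct a time tree from a phylo object
#'
#' Validates that the tree is rooted, has branch lengths on every non-root
#' edge, and is ultrametric within tolerance, then computes node ages
#' (tips at 0, root oldest).
#'
#' @param phy an [ape::phylo] object (or an existing `time_tree`, returned
#'   unchanged).
#' @param tol absolute tolerance for tip-age deviation from 0.  Default
#'   `1e-4` times the root age.  Trees failing the check are refused, never
#'   repaired: silently stretching tips would shift every richness timing.
#' @param annotations optional node annotations (list indexed by node id).
#' @return an object of class `time_tree`: list with elements `phy`, `ages`
#'   (numeric over all node ids), `n_tip`, `root`, `tol`, `annotations`.
#' @export
as_time_tree <- function(phy, tol = NULL, annotations = NULL) {
  if (inherits(phy, "time_tree")) return(phy)
  .assert(inherits(phy, "phylo"), "expected an ape 'phylo' object")
  n <- length(phy$tip.label)
  M <- n + phy$Nnode
  .assert(!is.null(phy$edge.length),
          "tree has no branch lengths; durations are required")
  bad <- which(!is.finite(phy$edge.length))
  if (length(bad)) {
    child <- phy$edge[bad[1], 2]
    nm <- if (child <= n) phy$tip.label[child] else paste("internal node", child)
    stop(sprintf("missing branch length on the edge leading to %s", nm),
         call. = FALSE)
  }
  .assert(all(phy$edge.length >= 0), "negative branch length found")
  parents <- unique(phy$edge[, 1])
  root <- setdiff(parents, phy$edge[, 2])
  .assert(length(root) == 1L, "tree is not rooted (no unique root)")
  depths <- ape::node.depth.edgelength(phy)
  H <- max(depths)
  tol. <- if (is.null(tol)) 1e-4 * H else tol
  dev <- H - depths[seq_len(n)]
  if (max(abs(dev)) > tol. + 1e-12) {
    worst <- which.max(abs(dev))
    stop(sprintf(
      "tree is not ultrametric within tolerance %g: tip '%s' sits %g below the deepest tip",
      tol., phy$tip.label[worst], dev[worst]), call. = FALSE)
  }
  ages <- H - depths
  ages[seq_len(n)] <- 0
  structure(list(phy = phy, ages = ages, n_tip = n, root = as.integer(root),
                 tol = tol., annotations = annotations),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, %d internal nodes, root age %.6g My\n",
              x$n_tip, x$phy$Nnode, x$ages[x$root]))
  if (!is.null(x$annotations))
    cat(sprintf("  annotations on %d nodes\n", length(x$annotations)))
  invisible(x)
}

#' Node ages of a time tree
#'
#' Ages are measured backward from the tips (tips at 0, root oldest), so
#' "older" always means a larger age.  For every child,
#' `age(parent) = age(child) + branch duration`.
#'
#' @param tree a `time_tree`, `phylo`, or Newick string.
#' @param tol see [as_time_tree()].
#' @return named numeric vector over all node ids; tips are named by their
#'   labels, internal nodes by their ids.
#' @export
node_ages <- function(tree, tol = NULL) {
  tt <- .coerce_tree(tree, tol = tol)
  ages <- tt$ages
  names(ages) <- c(tt$phy$tip.label,
                   as.character(tt$n_tip + seq_len(tt$phy$Nnode)))
  ages
}

# accept time_tree, phylo, newick text or a path
.coerce_tree <- function(tree, tol = NULL) {
  if (inherits(tree, "time_tree")) return(tree)
  if (inherits(tree, "phylo")) return(as_time_tree(tree, tol = tol))
  if (is.character(tree) && length(tree) == 1L)
    return(read_time_tree(text = tree, tol = tol))
  stop("cannot interpret 'tree' as a time tree", call. = FALSE)
}

# number of children of every node (0 for tips)
.n_children <- function(phy) {
  n <- length(phy$tip.label)
  tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
}

## ---------------------------------------------------------------------------
## parsing

#' Read a time-calibrated tree, keeping bracketed node annotations
#'
#' Accepts plain Newick or a NEXUS TREES block (the first tree is used, the
#' `translate` table is honoured).  BEAST-style metadata comments
#' (`[&key=value,key={v1,v2},...]`) attached to nodes or branch lengths are
#' parsed into per-node annotation lists with keys preserved verbatim;
#' comment-free input yields `annotations = NULL`.
#'
#' @param file path to a tree file; mutually exclusive with `text`.
#' @param text a Newick/NEXUS document as a single string.
#' @param tol ultrametricity tolerance, see [as_time_tree()].
#' @return a `time_tree`; annotations, if any, are in `$annotations`, a list
#'   indexed by node id.
#' @export
read_time_tree <- function(file = NULL, text = NULL, tol = NULL) {
  .assert(xor(is.null(file), is.null(text)),
          "supply exactly one of 'file' or 'text'")
  if (!is.null(file)) {
    .assert(file.exists(file), "no such file: %s", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    parsed <- .parse_nexus_tree(text)
  } else {
    parsed <- .parse_annotated_newick(text)
  }
  as_time_tree(parsed$phy, tol = tol, annotations = parsed$annotations)
}

# check parenthesis/quote balance, reporting the character offset on failure
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  inq <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") inq <- !inq
    if (inq) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (inq)
    stop("malformed Newick: unterminated quoted label", call. = FALSE)
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  invisible(TRUE)
}

.ANNO_RE <- "\\[&[^]]*\\]"

.parse_annotated_newick <- function(text) {
  text <- gsub("[\r\n]+", "", text)
  .check_newick_syntax(text)
  # drop non-metadata comments and leading rooting tags like [&R]
  text <- gsub("\\[&[RU]\\]", "", text)
  text <- gsub("\\[(?!&)[^]]*\\]", "", text, perl = TRUE)
  # move branch-length comments (":[&...]0.1") onto the node they subtend
  while (grepl(":\\[&", text))
    text <- sub("(:)(\\[&[^]]*\\])", "\\2\\1", text)
  m <- gregexpr(.ANNO_RE, text)[[1]]
  comments <- character(0)
  if (m[1] != -1L) {
    comments <- regmatches(text, gregexpr(.ANNO_RE, text))[[1]]
    markers <- sprintf(".Zanno%dZ.", seq_along(comments))
    regmatches(text, gregexpr(.ANNO_RE, text)) <- list(markers)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop(sprintf("Newick parse error: %s",
                                                   conditionMessage(e)),
                                           call. = FALSE))
  .assert(inherits(phy, "phylo"), "Newick parse error: no tree found")
  if (!length(comments)) return(list(phy = phy, annotations = NULL))

  n <- length(phy$tip.label)
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label)
  anno <- list()
  marker_re <- "\\.Zanno([0-9]+)Z\\."
  for (id in seq_along(labels)) {
    lab <- labels[id]
    hits <- regmatches(lab, gregexpr(marker_re, lab))[[1]]
    if (!length(hits)) next
    idx <- as.integer(sub(marker_re, "\\1", hits))
    fields <- list()
    for (k in idx) fields <- utils::modifyList(fields, .parse_comment(comments[k]))
    anno[[as.character(id)]] <- fields
    labels[id] <- gsub(marker_re, "", lab)
  }
  phy$tip.label <- labels[seq_len(n)]
  nl <- labels[n + seq_len(phy$Nnode)]
  phy$node.label <- if (all(nl == "")) NULL else nl
  list(phy = phy, annotations = if (length(anno)) anno else NULL)
}

# "[&posterior=0.98,location.set.prob={0.2,0.8}]" -> named list
.parse_comment <- function(comment) {
  body <- sub("^\\[&", "", sub("\\]$", "", comment))
  if (!nzchar(body)) return(list())
  parts <- .split_top_commas(body)
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L) { out[[p]] <- TRUE; next }
    key <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    if (grepl("^\\{.*\\}$", val)) {
      items <- .split_top_commas(sub("^\\{", "", sub("\\}$", "", val)))
      out[[key]] <- .num_or_char(gsub('^"|"$', "", trimws(items)))
    } else {
      out[[key]] <- .num_or_char(gsub('^"|"$', "", trimws(val)))
    }
  }
  out
}

.parse_nexus_tree <- function(text) {
  body <- gsub("\r", "", text)
  block <- regmatches(body, regexpr("(?is)begin\\s+trees\\s*;.*?end\\s*;",
                                    body, perl = TRUE))
  .assert(length(block) == 1L, "no TREES block found in NEXUS input")
  block <- block[[1]]
  translate <- NULL
  tr <- regmatches(block, regexpr("(?is)translate\\s+.*?;", block, perl = TRUE))
  if (length(tr)) {
    inner <- sub("(?is)^translate\\s+", "", sub(";$", "", tr[[1]]), perl = TRUE)
    pairs <- strsplit(trimws(.split_top_commas(inner)), "\\s+")
    translate <- stats::setNames(
      vapply(pairs, function(p) gsub("^'|'$", "", paste(p[-1], collapse = " ")),
             character(1)),
      vapply(pairs, `[[`, character(1), 1))
  }
  tree_m <- regmatches(
    block, regexpr("(?is)\\btree\\s+\\S+\\s*=\\s*[^;]*;", block, perl = TRUE))
  .assert(length(tree_m) >= 1L, "no tree statement found in TREES block")
  newick <- sub("(?is)^\\s*tree\\s+\\S+\\s*=\\s*", "", tree_m[[1]], perl = TRUE)
  parsed <- .parse_annotated_newick(newick)
  if (!is.null(translate)) {
    hit <- match(parsed$phy$tip.label, names(translate))
    parsed$phy$tip.label <- ifelse(is.na(hit), parsed$phy$tip.label,
                                   unname(translate[hit]))
  }
  parsed
}

## ---------------------------------------------------------------------------
## writing

.quote_label <- function(lab) {
  if (grepl("[](){},:;'\"\\[ \t]", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

.serialize_annotation <- function(fields) {
  items <- vapply(names(fields), function(k) {
    v <- fields[[k]]
    if (is.numeric(v) && length(v) > 1L)
      sprintf("%s={%s}", k, paste(format(v, digits = 15, scientific = FALSE,
                                         trim = TRUE), collapse = ","))
    else if (is.numeric(v))
      sprintf("%s=%s", k, format(v, digits = 15, scientific = FALSE, trim = TRUE))
    else if (is.character(v) && length(v) > 1L)
      sprintf("%s={%s}", k, paste(v, collapse = ","))
    else
      sprintf("%s=%s", k, as.character(v))
  }, character(1))
  sprintf("[&%s]", paste(items, collapse = ","))
}

#' Write a time tree as Newick, optionally with node annotations
#'
#' Annotations are emitted as BEAST-style bracketed comments placed after the
#' node (before the branch-length colon), so that [read_time_tree()] round
#' trips topology, durations and annotations.
#'
#' @param tree a `time_tree` or `phylo`.
#' @param file output path; if `NULL` the Newick string is returned.
#' @param annotations list indexed by node id; defaults to the tree's own.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to file.
#' @export
write_time_tree <- function(tree, file = NULL, annotations = NULL, digits = 12) {
  tt <- .coerce_tree(tree)
  if (is.null(annotations)) annotations <- tt$annotations
  phy <- tt$phy
  n <- tt$n_tip
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  fmt_len <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  node_str <- function(id, elen) {
    if (id <= n) {
      s <- .quote_label(phy$tip.label[id])
    } else {
      sub_edges <- kids[[as.character(id)]]
      subs <- vapply(sub_edges, function(e)
        node_str(phy$edge[e, 2], phy$edge.length[e]), character(1))
      lab <- if (!is.null(phy$node.label)) phy$node.label[id - n] else ""
      s <- sprintf("(%s)%s", paste(subs, collapse = ","),
                   if (is.null(lab) || is.na(lab) || !nzchar(lab)) "" else .quote_label(lab))
    }
    a <- annotations[[as.character(id)]]
    if (!is.null(a) && length(a)) s <- paste0(s, .serialize_annotation(a))
    if (!is.na(elen)) s <- paste0(s, ":", fmt_len(elen))
    s
  }
  out <- paste0(node_str(tt$root, NA_real_), ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

## ---------------------------------------------------------------------------
## state-probability tables

# descendant tip-label set of every internal node, keyed for clade matching
.clade_keys <- function(tt) {
  phy <- tt$phy
  n <- tt$n_tip
  M <- n + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", M)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}

.new_state_posterior <- function(mat, regions) {
  colnames(mat) <- unname(regions)
  rownames(mat) <- as.character(seq_len(nrow(mat)))
  structure(mat, regions = unname(regions), class = c("state_posterior", "matrix"))
}

# renormalize a probability vector; deviation beyond `hard` is refused
.normalize_prob <- function(p, what, soft = 1e-3, hard = 0.05) {
  .assert(all(is.finite(p)) && all(p >= 0),
          "invalid probability vector for %s", what)
  s <- sum(p)
  if (abs(s - 1) > hard)
    stop(sprintf("probability vector for %s sums to %.4g (beyond %.2g of 1); refusing",
                 what, s, hard), call. = FALSE)
  p / s
}

#' Attach per-node region probabilities from a sidecar table
#'
#' Rows are matched to internal nodes either by a `node` column (ape node
#' ids) or by a `clade` column listing the descendant tip labels (separated
#' by `,`, `;` or `|`); clade matching is the robust fallback when node
#' numberings differ between producers.  Every internal node must be matched
#' exactly once.  Vectors are renormalized when their sum is within 0.05 of
#' 1 and refused beyond that.
#'
#' @param tree a `time_tree` (or coercible).
#' @param table data frame with `node` or `clade` plus one column per region.
#' @param regions ordered region labels, default [default_regions()].
#' @param tip_regions optional named character vector (tip label -> region)
#'   from which tips receive one-hot vectors; tips are `NA` otherwise.
#' @return a `state_posterior`: numeric matrix, one row per node id, one
#'   column per region.
#' @export
attach_state_probabilities <- function(tree, table, regions = default_regions(),
                                       tip_regions = NULL) {
  tt <- .coerce_tree(tree)
  regions <- as_region_set(regions)
  K <- length(regions)
  .assert(is.data.frame(table), "'table' must be a data frame")
  .assert(all(unname(regions) %in% names(table)),
          "table lacks a column for each region (%s)",
          paste(regions, collapse = ", "))
  n <- tt$n_tip
  M <- n + tt$phy$Nnode
  internal <- n + seq_len(tt$phy$Nnode)

  if ("node" %in% names(table)) {
    ids <- as.integer(table$node)
    .assert(!anyNA(ids), "non-integer entries in 'node' column")
  } else if ("clade" %in% names(table)) {
    keys <- .clade_keys(tt)
    want <- vapply(strsplit(as.character(table$clade), "[,;|]\\s*"),
                   function(s) paste(sort(trimws(s)), collapse = "|"),
                   character(1))
    ids <- match(want, keys)
    if (anyNA(ids)) {
      miss <- table$clade[which(is.na(ids))[1]]
      stop(sprintf("clade {%s} matches no node in the tree", miss), call. = FALSE)
    }
  } else {
    stop("table needs a 'node' or 'clade' column", call. = FALSE)
  }
  .assert(!anyDuplicated(ids), "node %s matched by more than one table row",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing_internal <- setdiff(internal, ids)
  if (length(missing_internal)) {
    keys <- .clade_keys(tt)
    stop(sprintf("internal node %d (tips: %s) has no probability row",
                 missing_internal[1],
                 gsub("\\|", ", ", keys[missing_internal[1]])), call. = FALSE)
  }

  mat <- matrix(NA_real_, M, K)
  for (r in seq_along(ids)) {
    p <- as.numeric(table[r, unname(regions)])
    mat[ids[r], ] <- .normalize_prob(p, sprintf("node %d", ids[r]))
  }
  if (!is.null(tip_regions)) {
    hit <- match(tt$phy$tip.label, names(tip_regions))
    .assert(!anyNA(hit), "tip '%s' missing from tip_regions",
            tt$phy$tip.label[which(is.na(hit))[1]])
    reg_idx <- match(unname(tip_regions[hit]), unname(regions))
    .assert(!anyNA(reg_idx), "tip region not in the region set")
    for (i in seq_len(n)) {
      mat[i, ] <- 0
      mat[i, reg_idx[i]] <- 1
    }
  }
  .new_state_posterior(mat, regions)
}

#' Convert a substitution-scaled tree to a time tree with a strict clock
#'
#' Every branch duration becomes substitution length / rate.  With an
#' interval rate `c(lower, upper)` (substitutions per site and My) two trees
#' are returned: the lower rate yields the older ages.
#'
#' @param tree tree with branch lengths in substitutions/site.
#' @param rate positive scalar, or length-2 interval, in
#'   substitutions / site / My.
#' @return a `time_tree`, or for an interval a list with elements `older`
#'   (lower rate) and `younger` (upper rate) plus a `rates` attribute.
#' @export
scale_to_time <- function(tree, rate) {
  phy <- if (inherits(tree, "time_tree")) tree$phy else tree
  .assert(inherits(phy, "phylo"), "expected a phylo or time_tree")
  .assert(is.numeric(rate) && length(rate) %in% 1:2 && all(rate > 0),
          "clock rate must be positive (scalar or interval)")
  one <- function(r) {
    p <- phy
    p$edge.length <- p$edge.length / r
    as_time_tree(p)
  }
  if (length(rate) == 1L) return(one(rate))
  rate <- sort(rate)
  structure(list(older = one(rate[1]), younger = one(rate[2])),
            rates = rate)
}

#' Write a node-diversity table as TSV
#'
#' Columns: node id, mean age, 95% CI bounds, support, one probability
#' column per region, lineage diversity.  Estimates are printed to three
#' significant figures; support values are passed through unrounded.
#' Unprocessed nodes (maximum location probability below the threshold)
#' keep their row but have a blank diversity field.  Convention settings
#' travel as `#`-prefixed metadata comment lines.
#'
#' @param records a data frame as produced by [diversity_table()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_node_table <- function(records, file) {
  regions <- attr(records, "regions")
  if (is.null(regions))
    regions <- setdiff(names(records),
                       c("node", "age_mean", "age_lower", "age_upper",
                         "support", "lineage_diversity", "processed"))
  out <- data.frame(node = records$node, check.names = FALSE)
  out$age_mean <- fmt_sig3(records$age_mean)
  out$age_lower <- fmt_sig3(records$age_lower)
  out$age_upper <- fmt_sig3(records$age_upper)
  out$support <- ifelse(is.na(records$support), "",
                        as.character(records$support))
  for (r in regions) out[[r]] <- fmt_sig3(records[[r]])
  div <- records$lineage_diversity
  if (!is.null(records$processed)) div[!records$processed] <- NA_real_
  out$lineage_diversity <- fmt_sig3(div)

  con <- file(file, open = "wt")
  on.exit(close(con))
  meta <- attr(records, "conventions")
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), unlist(meta)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
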