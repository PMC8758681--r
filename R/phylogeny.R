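# Maximum-parsimony phylogeny over region character matrices.
#
# Trees are rooted at an inferred normal diploid ancestor (all-neutral state
# vector) attached by a trunk edge to the most recent common ancestor of the
# regions. Characters take values in {-1, 0, +1}; NA is undetermined and acts
# as a wildcard (no cost, any state). Scoring is a per-column Sankoff dynamic
# program with unit substitution costs, which handles the fixed root state
# exactly.

.mp_states <- c(-1L, 0L, 1L)

.topo_leaves <- function(topo) {
  if (!is.list(topo)) return(topo)
  c(.topo_leaves(topo[[1L]]), .topo_leaves(topo[[2L]]))
}

.n_leaves <- function(topo) if (!is.list(topo)) 1L else
  .n_leaves(topo[[1L]]) + .n_leaves(topo[[2L]])

# Sankoff cost matrix (3 states x columns) of a subtree.
.sankoff_cost <- function(topo, X) {
  if (!is.list(topo)) {
    obs <- X[topo, ]
    C <- matrix(Inf, nrow = 3L, ncol = ncol(X))
    for (s in 1:3) C[s, is.na(obs) | obs == .mp_states[s]] <- 0
    return(C)
  }
  cl <- .sankoff_cost(topo[[1L]], X)
  cr <- .sankoff_cost(topo[[2L]], X)
  contrib <- function(C) {
    m <- pmin(C[1L, ], C[2L, ], C[3L, ]) + 1
    rbind(pmin(C[1L, ], m), pmin(C[2L, ], m), pmin(C[3L, ], m))
  }
  contrib(cl) + contrib(cr)
}

.check_matrix <- function(matrix) {
  if (!is.matrix(matrix) || is.null(rownames(matrix))) {
    stop("character matrix must have region row names")
  }
  vals <- matrix[!is.na(matrix)]
  if (length(vals) > 0L && !all(vals %in% .mp_states)) {
    stop("character values must be in {-1, 0, +1} or NA")
  }
  invisible(matrix)
}

#' Parsimony score of a topology under a diploid root
#'
#' Minimum number of character state changes needed to explain the matrix on
#' the given rooted topology, summed over columns, with the root constrained
#' to the all-neutral (0) diploid state. Undetermined (NA) entries are
#' wildcards: they impose no cost and can take any state.
#'
#' @param topology A nested-list topology (leaf = region name, internal node =
#'   `list(left, right)`), a `phylo_tree`, or an `ape::phylo` object whose tip
#'   labels are matrix rows.
#' @param matrix A `character_matrix` (rows = regions, values -1/0/+1/NA).
#' @return Non-negative integer score.
#' @examples
#' m <- rbind(A = c(-1, 0), B = c(-1, -1), C = c(0, 0))
#' parsimony_score(list(list("A", "B"), "C"), m) # 2
#' @export
parsimony_score <- function(topology, matrix) {
  .check_matrix(matrix)
  topo <- .as_topology(topology)
  leaves <- .topo_leaves(topo)
  missing_rows <- setdiff(leaves, rownames(matrix))
  if (length(missing_rows) > 0L) {
    stop("leaf without a matrix row: ", missing_rows[1L])
  }
  if (anyDuplicated(leaves)) stop("duplicate leaf labels in topology")
  C <- .sankoff_cost(topo, matrix)
  colmin <- pmin(C[1L, ], C[2L, ], C[3L, ])
  sum(pmin(C[2L, ], colmin + 1))  # root forced to neutral
}

.as_topology <- function(x) {
  if (inherits(x, "phylo_tree")) return(x$topology)
  if (inherits(x, "phylo")) return(.phylo_to_nested(x))
  if (is.character(x) && length(x) == 1L) return(x)
  if (is.list(x)) {
    if (length(x) != 2L) stop("internal topology nodes must be binary")
    return(list(.as_topology(x[[1L]]), .as_topology(x[[2L]])))
  }
  stop("unsupported topology representation")
}

.phylo_to_nested <- function(tr) {
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  rec <- function(node) {
    if (node <= n_tip) return(tr$tip.label[node])
    ch <- kids[[as.character(node)]]
    if (length(ch) != 2L) stop("tree must be binary to score as a rooted topology")
    list(rec(ch[1L]), rec(ch[2L]))
  }
  rec(n_tip + 1L)
}

.canon <- function(topo) {
  if (!is.list(topo)) return(topo)
  s <- sort(c(.canon(topo[[1L]]), .canon(topo[[2L]])))
  paste0("(", s[1L], ",", s[2L], ")")
}

# Insert `leaf` on the pos-th edge of `topo` in preorder (edge 1 = edge above
# the subtree root). A subtree with m leaves exposes 2m - 1 edges.
.insert_edge <- function(topo, leaf, pos) {
  if (pos == 1L) return(list(topo, leaf))
  pos <- pos - 1L
  nl <- 2L * .n_leaves(topo[[1L]]) - 1L
  if (pos <= nl) {
    topo[[1L]] <- .insert_edge(topo[[1L]], leaf, pos)
  } else {
    topo[[2L]] <- .insert_edge(topo[[2L]], leaf, pos - nl)
  }
  topo
}

#' Maximum-parsimony tree by exhaustive rooted-topology search
#'
#' Enumerates every rooted binary topology over the matrix rows — (2n-3)!!
#' trees for n regions — scores each with the diploid-rooted Sankoff criterion
#' of [parsimony_score()], and returns a minimum-score tree. Ties between
#' co-optimal topologies are broken deterministically by the lexicographically
#' smallest canonical newick string, and the number of co-optimal topologies
#' is always reported so ambiguity stays visible.
#'
#' Ancestral states, branch lengths and per-branch events are filled in via
#' [assign_branch_events()].
#'
#' @param matrix A `character_matrix` with 2 to 8 region rows.
#' @return A `phylo_tree`: list with `topology`, `newick` (canonical, diploid
#'   ancestor as root), `score`, `n_co_optimal`, `leaves`, plus the `states`
#'   and `branches` filled by event assignment.
#' @export
build_mp_tree <- function(matrix) {
  .check_matrix(matrix)
  leaves <- rownames(matrix)
  n <- length(leaves)
  if (n < 2L) stop("need at least 2 regions")
  if (n > 8L) {
    stop("exhaustive search is limited to 8 regions; reduce the matrix ",
         "(e.g. merge indistinguishable regions) before building a tree")
  }

  best_score <- Inf
  best_canon <- NULL
  best_topo <- NULL
  n_opt <- 0L

  radix <- if (n >= 3L) 2L * (3:n) - 3L else integer(0)
  counter <- rep(1L, length(radix))
  repeat {
    topo <- list(leaves[1L], leaves[2L])
    for (k in seq_along(radix)) {
      topo <- .insert_edge(topo, leaves[k + 2L], counter[k])
    }
    sc <- parsimony_score(topo, matrix)
    if (sc < best_score - 1e-9) {
      best_score <- sc
      best_topo <- topo
      best_canon <- .canon(topo)
      n_opt <- 1L
    } else if (sc <= best_score + 1e-9) {
      n_opt <- n_opt + 1L
      cn <- .canon(topo)
      if (cn < best_canon) {
        best_canon <- cn
        best_topo <- topo
      }
    }
    # advance mixed-radix counter
    k <- length(counter)
    while (k > 0L) {
      counter[k] <- counter[k] + 1L
      if (counter[k] <= radix[k]) break
      counter[k] <- 1L
      k <- k - 1L
    }
    if (k == 0L) break
  }

  tree <- structure(
    list(topology = best_topo, newick = paste0("(", best_canon, ")diploid_ancestor;"),
         score = as.integer(round(best_score)), n_co_optimal = n_opt,
         leaves = leaves),
    class = "phylo_tree"
  )
  assign_branch_events(tree, matrix)
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("phylo_tree:", x$newick, "\n")
  cat(sprintf("  parsimony score %d (%d co-optimal topolog%s)\n", x$score,
              x$n_co_optimal, if (x$n_co_optimal == 1L) "y" else "ies"))
  if (!is.null(x$branches)) {
    ev <- vapply(x$branches$events, length, integer(1L))
    cat(sprintf("  %d branches, total length %d, %d placed events, %d unplaced\n",
                nrow(x$branches), sum(x$branches$length), sum(ev),
                length(x$unplaced)))
  }
  invisible(x)
}

# Flatten a nested topology (with the diploid ancestor prepended) into node
# tables: preorder ids, node 1 = diploid ancestor, node 2 = in-group root.
.tree_nodes <- function(topo) {
  labels <- character(1L); labels[1L] <- "diploid_ancestor"
  parents <- NA_integer_
  child_list <- list(integer(0))
  rec <- function(node, parent) {
    id <- length(labels) + 1L
    labels[id] <<- if (is.list(node)) "" else node
    parents[id] <<- parent
    child_list[[id]] <<- integer(0)
    child_list[[parent]] <<- c(child_list[[parent]], id)
    if (is.list(node)) {
      rec(node[[1L]], id)
      rec(node[[2L]], id)
    }
  }
  rec(topo, 1L)
  list(label = labels, parent = parents, children = child_list)
}

#' Assign ancestral states, branch lengths and events to a parsimony tree
#'
#' Fixes ancestral character states by a root-to-tip pass over the Sankoff
#' cost matrices, preferring the neutral state on ties (events are thereby
#' biased later, the conservative reading of a normal diploid ancestor). Each
#' branch then carries (i) a length — the Hamming distance between its
#' endpoint state vectors, skipping positions where the child's observation is
#' undetermined — and (ii) the list of segment characters whose state changes
#' on that branch.
#'
#' When a mutation `presence` matrix is supplied (rows = regions, values
#' `"present"`, `"absent"` or `"unknown"`), each mutation is placed on the
#' edge above the most recent common ancestor of its present regions, provided
#' that clade contains no region where it is absent; mutations present in all
#' regions map to the trunk. Presence patterns incompatible with any single
#' branch (homoplasy) are flagged in `$unplaced`, not dropped.
#'
#' @param tree A `phylo_tree` built over `matrix`.
#' @param matrix The `character_matrix` the tree was built from.
#' @param presence Optional regions x mutations matrix of presence calls.
#' @return The `phylo_tree` with `states` (nodes x characters), `branches`
#'   (data frame: parent, child, label, length, events list-column) and
#'   `unplaced` filled in.
#' @export
assign_branch_events <- function(tree, matrix, presence = NULL) {
  stopifnot(inherits(tree, "phylo_tree"))
  .check_matrix(matrix)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("char", seq_len(ncol(matrix)))
  }
  nd <- .tree_nodes(tree$topology)
  n_nodes <- length(nd$label)
  ncol_m <- ncol(matrix)

  # bottom-up cost matrices (preorder ids: children follow parents)
  costs <- vector("list", n_nodes)
  for (id in n_nodes:2) {
    if (length(nd$children[[id]]) == 0L) {
      obs <- matrix[nd$label[id], ]
      C <- matrix(Inf, nrow = 3L, ncol = ncol_m)
      for (s in 1:3) C[s, is.na(obs) | obs == .mp_states[s]] <- 0
    } else {
      contrib <- function(C) {
        m <- pmin(C[1L, ], C[2L, ], C[3L, ]) + 1
        rbind(pmin(C[1L, ], m), pmin(C[2L, ], m), pmin(C[3L, ], m))
      }
      ch <- nd$children[[id]]
      C <- contrib(costs[[ch[1L]]]) + contrib(costs[[ch[2L]]])
    }
    costs[[id]] <- C
  }

  # top-down state assignment; diploid ancestor forced to 0
  states <- matrix(0L, nrow = n_nodes, ncol = ncol_m)
  rownames(states) <- ifelse(nd$label == "", paste0("node", seq_len(n_nodes)),
                             nd$label)
  colnames(states) <- colnames(matrix)
  pref <- c(2L, 1L, 3L)  # tie preference: 0, then -1, then +1
  for (id in 2:n_nodes) {
    p <- states[nd$parent[id], ]
    C <- costs[[id]]
    pidx <- match(p, .mp_states)
    for (j in seq_len(ncol_m)) {
      cand <- C[, j] + (seq_len(3L) != pidx[j])
      order_idx <- unique(c(pref[cand[pref] == min(cand)][1L],
                            which.min(cand)))
      states[id, j] <- .mp_states[order_idx[1L]]
    }
  }

  # branch table
  branch_child <- 2:n_nodes
  lengths <- integer(length(branch_child))
  events <- vector("list", length(branch_child))
  for (b in seq_along(branch_child)) {
    id <- branch_child[b]
    ps <- states[nd$parent[id], ]
    cs <- states[id, ]
    usable <- rep(TRUE, ncol_m)
    if (length(nd$children[[id]]) == 0L) {
      usable <- !is.na(matrix[nd$label[id], ])
    }
    changed <- usable & (ps != cs)
    lengths[b] <- sum(changed)
    ev <- character(0)
    if (any(changed)) {
      ev <- sprintf("%s:%+d", colnames(matrix)[changed], cs[changed])
    }
    events[[b]] <- ev
  }

  branches <- data.frame(
    parent = nd$parent[branch_child],
    child = branch_child,
    label = ifelse(nd$label[branch_child] == "",
                   paste0("node", branch_child), nd$label[branch_child]),
    length = lengths,
    stringsAsFactors = FALSE
  )
  branches$events <- events

  unplaced <- character(0)
  if (!is.null(presence)) {
    if (is.logical(presence)) {
      presence <- ifelse(presence, "present", "absent")
    }
    if (is.null(rownames(presence)) ||
        !all(tree$leaves %in% rownames(presence))) {
      stop("presence matrix rows must cover all tree leaves")
    }
    # descendant leaf sets per node
    desc <- vector("list", n_nodes)
    for (id in n_nodes:1) {
      desc[[id]] <- if (length(nd$children[[id]]) == 0L && id > 1L) {
        nd$label[id]
      } else {
        unlist(lapply(nd$children[[id]], function(c) desc[[c]]))
      }
    }
    for (m in colnames(presence)) {
      pres <- tree$leaves[presence[tree$leaves, m] == "present"]
      abs_ <- tree$leaves[presence[tree$leaves, m] == "absent"]
      if (length(pres) == 0L) next
      # deepest node whose clade contains all present leaves
      cand <- which(vapply(desc, function(d) all(pres %in% d), logical(1L)))
      mrca <- cand[which.max(vapply(cand, function(i) -length(desc[[i]]),
                                    numeric(1L)))]
      if (mrca == 1L) mrca <- 2L  # trunk edge carries fully clonal mutations
      if (any(abs_ %in% desc[[mrca]])) {
        unplaced <- c(unplaced, m)
      } else {
        b <- which(branches$child == mrca)
        branches$events[[b]] <- c(branches$events[[b]], paste0("mut:", m))
      }
    }
  }

  tree$states <- states
  tree$branches <- branches
  tree$unplaced <- unplaced
  tree$node_parent <- nd$parent
  tree
}

#' Write a parsimony tree as newick text
#'
#' Branch lengths are the integer Hamming distances; each branch with events
#' carries a `[&events=...]` comment. The diploid ancestor is the (single
#' child) root node.
#'
#' @param tree A `phylo_tree` with branches assigned.
#' @param file Optional path; when omitted the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo_tree"), !is.null(tree$branches))
  br <- tree$branches
  kids <- split(br$child, br$parent)
  fmt <- function(id) {
    b <- which(br$child == id)
    suffix <- sprintf(":%d", br$length[b])
    if (length(br$events[[b]]) > 0L) {
      suffix <- paste0(suffix, sprintf("[&events=%s]",
                                       paste(br$events[[b]], collapse = "|")))
    }
    ch <- kids[[as.character(id)]]
    if (is.null(ch)) return(paste0(br$label[b], suffix))
    paste0("(", paste(vapply(sort(ch), fmt, character(1L)), collapse = ","),
           ")", suffix)
  }
  nwk <- paste0("(", fmt(2L), ")diploid_ancestor;")
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
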