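#' Construct a clone tree from a parent vector
#'
#' A clone tree has one node per mutation plus a wild-type root; each
#' clone's mutation set is the path from the root to its node, so sets are
#' strictly nested along any branch and mutually exclusive mutations sit on
#' different branches.
#'
#' @param parent Integer vector: \code{parent[i]} is the parent node of
#'   mutation \code{i}, with 0 denoting the WT root.
#' @param mutations Character vector of mutation identifiers.
#' @return Object of class \code{clone_tree}: list with \code{parent},
#'   \code{mutations}, \code{clones} (list of mutation-index sets per node,
#'   root first) and \code{clone_ids}.
#' @export
clone_tree <- function(parent, mutations) {
  m <- length(mutations)
  stopifnot(length(parent) == m, all(parent %in% 0:m))
  # path from root for each node; also detects cycles
  sets <- vector("list", m + 1)
  sets[[1]] <- integer(0)
  path_of <- function(i) {
    seen <- integer(0)
    j <- i
    while (j != 0) {
      if (j %in% seen) stop("cycle in clone tree", call. = FALSE)
      seen <- c(j, seen)
      j <- parent[j]
    }
    seen
  }
  for (i in seq_len(m)) sets[[i + 1]] <- path_of(i)
  ids <- c("WT", vapply(seq_len(m), function(i) {
    paste(mutations[sets[[i + 1]]], collapse = "+")
  }, character(1)))
  structure(list(parent = as.integer(parent), mutations = mutations,
                 clones = sets, clone_ids = ids),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree>", length(x$mutations), "mutation(s)\n")
  depth <- function(i) length(x$clones[[i + 1]])
  ord <- order(vapply(seq_along(x$mutations), depth, numeric(1)))
  cat("  WT (root)\n")
  show <- function(node, indent) {
    kids <- which(x$parent == node)
    for (k in kids) {
      cat(strrep("  ", indent + 1), x$mutations[k], "\n", sep = "")
      show(k, indent + 1)
    }
  }
  show(0L, 0L)
  invisible(x)
}

#' @keywords internal
#' Decode a Pruefer sequence over nodes 1..n into an edge list (n >= 3).
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, nrow = n - 1, ncol = 2)
  ptr <- 0L
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- 0L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

#' @keywords internal
#' All rooted mutation trees on m mutations (root = node m+1, the WT clone),
#' as a list of parent vectors (0 = root).
enumerate_trees <- function(m) {
  n <- m + 1L
  root <- n
  orient <- function(edges) {
    adj <- vector("list", n)
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    parent <- rep(0L, n)
    queue <- root
    visited <- rep(FALSE, n)
    visited[root] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    p <- parent[seq_len(m)]
    p[p == root] <- 0L
    p
  }
  if (m == 1) return(list(0L))
  if (m == 2) {
    # trees on 3 nodes: star at each node
    return(lapply(list(c(0L, 0L), c(0L, 1L), c(2L, 0L)), identity))
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(i) {
    orient(prufer_to_edges(seqs[i, ], n))
  })
}

#' @keywords internal
#' Log-likelihood of an observed genotype matrix under a clone tree with
#' per-entry errors, marginalizing each cell over uniform attachment.
tree_loglik <- function(tree, mat, fd, ad) {
  m <- length(tree$mutations)
  n_clones <- m + 1L
  # truth matrix: clones x mutations
  truth <- matrix(0L, nrow = n_clones, ncol = m)
  for (ci in seq_len(n_clones)) truth[ci, tree$clones[[ci]]] <- 1L
  total <- 0
  for (cell in seq_len(nrow(mat))) {
    obs <- mat[cell, ]
    lik_clone <- vapply(seq_len(n_clones), function(ci) {
      tr <- truth[ci, ]
      p <- ifelse(is.na(obs), 1,
                  ifelse(tr == 1,
                         ifelse(obs == 1, 1 - ad, ad),
                         ifelse(obs == 1, fd, 1 - fd)))
      prod(p)
    }, numeric(1))
    total <- total + log(mean(lik_clone))
  }
  total
}

#' Infer the maximum-likelihood clone tree by exhaustive enumeration
#'
#' Scores every rooted mutation tree (one node per mutation plus the WT
#' root) against the observed cells-by-mutations genotype matrix under a
#' per-entry error model: a spurious MUT observation occurs with the
#' false-positive rate, a missed MUT with the dropout rate, and MISSING
#' entries are marginalized. Each cell attaches to one clone; its
#' likelihood is the average over attachment points. With at most 6
#' mutations the tree space (at most \eqn{7^5 = 16807} trees) is searched
#' exhaustively, so the returned tree is the global maximum-likelihood
#' solution. Equally likely trees are broken toward fewer branches (linear
#' over branching), then lexicographic parent order; ties are reported.
#'
#' @param mat Matrix or data.frame, cells x mutations, entries 1 (MUT),
#'   0 (WT) or \code{NA} (missing/undetermined). Column names are the
#'   mutation identifiers.
#' @param false_positive_rate Probability of a spurious MUT entry.
#' @param ado_rate Probability a truly present mutation is observed WT.
#' @return List: \code{tree} (a [clone_tree()]), \code{loglik},
#'   \code{n_ties}, \code{clone_counts} (exact-match cells per clone).
#' @export
infer_clone_tree <- function(mat, false_positive_rate = 0.01,
                             ado_rate = 0.02) {
  mat <- as.matrix(mat)
  mode(mat) <- "numeric"
  m <- ncol(mat)
  if (m > 6) {
    stop("more than 6 mutations: exhaustive enumeration is infeasible; ",
         "use an MCMC tree-search tool", call. = FALSE)
  }
  if (all(is.na(mat))) {
    stop("genotype matrix is entirely missing", call. = FALSE)
  }
  muts <- colnames(mat)
  if (is.null(muts)) muts <- paste0("M", seq_len(m))
  fd <- false_positive_rate
  ad <- ado_rate
  stopifnot(fd > 0, fd < 1, ad > 0, ad < 1)

  parents <- enumerate_trees(m)
  trees <- lapply(parents, clone_tree, mutations = muts)
  ll <- vapply(trees, tree_loglik, numeric(1), mat = mat, fd = fd, ad = ad)
  best <- max(ll)
  cand <- which(ll >= best - 1e-9)
  n_ties <- length(cand)
  if (n_ties > 1) {
    n_branch <- vapply(cand, function(i) {
      sum(table(parents[[i]]) > 1)  # nodes (incl. root) with > 1 child
    }, numeric(1))
    cand <- cand[order(n_branch,
                       vapply(cand, function(i) {
                         paste(parents[[i]], collapse = ",")
                       }, character(1)))]
  }
  tree <- trees[[cand[1]]]

  # exact-genotype cell counts per clone (consistency report)
  key <- apply(mat, 1, function(r) paste(ifelse(is.na(r), "?", r),
                                         collapse = ""))
  clone_key <- vapply(tree$clones, function(s) {
    v <- rep(0L, m); v[s] <- 1L; paste(v, collapse = "")
  }, character(1))
  clone_counts <- vapply(clone_key, function(k) sum(key == k), numeric(1))
  names(clone_counts) <- tree$clone_ids

  list(tree = tree, loglik = best, n_ties = n_ties,
       clone_counts = clone_counts)
}

#' Assign each cell to a clone of an inferred tree
#'
#' A cell belongs to the unique clone whose mutation set matches its
#' detected MUT calls; UNDETERMINED loci are uninformative. When no clone
#' matches exactly but one matches after assuming that up to
#' \code{max_ancestral_ado} ancestral mutations went undetected (called WT
#' despite being present), the cell is rescued into the deepest consistent
#' clone — dropout of an ancestor is the observed failure mode, whereas a
#' detected descendant cannot have dropped out. Cells with no unique
#' consistent clone are unassignable and excluded downstream.
#'
#' @param mat Cells x mutations matrix with entries 1 (MUT), 0 (WT),
#'   \code{NA} (undetermined); rownames are cell identifiers.
#' @param tree A [clone_tree()].
#' @param max_ancestral_ado Maximum ancestral dropout events assumed.
#' @return data.frame: cell_id, clone_id, n_inferred_ancestral_ados,
#'   confidence ("exact", "ado_rescued" or "unassignable").
#' @export
assign_cells <- function(mat, tree, max_ancestral_ado = 1) {
  mat <- as.matrix(mat)
  mode(mat) <- "numeric"
  m <- ncol(mat)
  stopifnot(m == length(tree$mutations))
  cells <- rownames(mat)
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(mat)))

  n_clones <- m + 1L
  res <- lapply(seq_len(nrow(mat)), function(i) {
    obs <- mat[i, ]
    det <- which(!is.na(obs) & obs == 1)
    wt <- which(!is.na(obs) & obs == 0)
    # per clone: consistent iff detected MUT set is a subset of the clone
    # set; clone mutations called WT count as inferred ancestral dropouts
    n_ado <- rep(NA_integer_, n_clones)
    for (ci in seq_len(n_clones)) {
      s <- tree$clones[[ci]]
      if (!all(det %in% s)) next
      n_ado[ci] <- sum(s %in% wt)
    }
    ok <- which(!is.na(n_ado) & n_ado <= max_ancestral_ado)
    exact <- ok[n_ado[ok] == 0]
    if (length(exact)) {
      # among zero-ADO clones the true clone is the deepest whose set the
      # observations cannot distinguish; unique only if one candidate
      if (length(exact) == 1) {
        ci <- exact
        return(data.frame(cell_id = cells[i],
                          clone_id = tree$clone_ids[ci],
                          n_inferred_ancestral_ados = 0L,
                          confidence = "exact",
                          stringsAsFactors = FALSE))
      }
      return(data.frame(cell_id = cells[i], clone_id = NA_character_,
                        n_inferred_ancestral_ados = NA_integer_,
                        confidence = "unassignable",
                        stringsAsFactors = FALSE))
    }
    if (length(ok)) {
      depth <- lengths(tree$clones)[ok]
      deepest <- ok[depth == max(depth)]
      if (length(deepest) == 1) {
        ci <- deepest
        return(data.frame(cell_id = cells[i],
                          clone_id = tree$clone_ids[ci],
                          n_inferred_ancestral_ados = n_ado[ci],
                          confidence = "ado_rescued",
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(cell_id = cells[i], clone_id = NA_character_,
               n_inferred_ancestral_ados = NA_integer_,
               confidence = "unassignable", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a cells-by-mutations genotype matrix from consensus calls
#'
#' @param calls Consensus call table from [call_genotypes()] (possibly
#'   after [ado_analysis()] rescue).
#' @return Numeric matrix, cells x mutations: 1 = MUT, 0 = WT,
#'   \code{NA} = UNDETERMINED or absent.
#' @export
genotype_matrix <- function(calls) {
  cells <- unique(calls$cell_id)
  muts <- unique(calls$mutation_id)
  mat <- matrix(NA_real_, nrow = length(cells), ncol = length(muts),
                dimnames = list(cells, muts))
  v <- ifelse(calls$consensus == "MUT", 1,
              ifelse(calls$consensus == "WT", 0, NA_real_))
  mat[cbind(match(calls$cell_id, cells), match(calls$mutation_id, muts))] <- v
  mat
}

#' Newick rendering of a clone tree
#'
#' Serializes the clone tree with clone identifiers as node labels,
#' optionally annotated with per-clone cell counts.
#'
#' @param tree A [clone_tree()].
#' @param counts Optional named vector of cell counts per clone_id.
#' @return Single newick string (terminated by ";").
#' @export
clone_tree_newick <- function(tree, counts = NULL) {
  lab <- function(node) {
    id <- tree$clone_ids[node + 1]
    id <- gsub("[ ,;:()]", "_", id)
    if (!is.null(counts) && tree$clone_ids[node + 1] %in% names(counts)) {
      id <- paste0(id, "_n", counts[[tree$clone_ids[node + 1]]])
    }
    id
  }
  render <- function(node) {
    kids <- which(tree$parent == node)
    if (!length(kids)) return(lab(node))
    paste0("(", paste(vapply(kids, render, character(1)), collapse = ","),
           ")", lab(node))
  }
  paste0(render(0L), ";")
}

#' Write a clone tree as an indented listing plus newick
#'
#' @param tree A [clone_tree()].
#' @param path Output file.
#' @param counts Optional named cell counts per clone.
#' @return The path, invisibly.
#' @export
write_clone_tree <- function(tree, path, counts = NULL) {
  lines <- character(0)
  walk <- function(node, indent) {
    id <- tree$clone_ids[node + 1]
    extra <- if (!is.null(counts) && id %in% names(counts)) {
      paste0("  [", counts[[id]], " cells]")
    } else ""
    lines <<- c(lines, paste0(strrep("  ", indent), id, extra))
    for (k in which(tree$parent == node)) walk(k, indent + 1)
  }
  walk(0L, 0L)
  writeLines(c(lines, "", clone_tree_newick(tree, counts)), path)
  invisible(path)
}
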