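#' Encode dosage calls as cumulative binary band ladders
#'
#' Each locus contributes `10 / bin_width` ordered indicators; indicator
#' `i` is 1 iff the presence score reaches `i * bin_width`. With the
#' default `bin_width = 1` a score of 6 becomes `1111110000`. This
#' cumulative "band ladder" lets nearby dosages have small but nonzero
#' distances, which a plain presence/absence bit per locus cannot express.
#' Loci with missing scores (status `inconclusive` or `repeat_needed`
#' without scores) contribute an all-zero block.
#'
#' @param calls Dosage call table from [call_dosage()] (columns `sample`,
#'   `locus`, `presence_score`).
#' @param bin_width Score units per indicator; must divide 10 evenly.
#' @returns A 0/1 matrix, one row per sample (rownames = sample ids),
#'   columns ordered by locus then threshold; locus ids attached as
#'   attribute `"loci"`.
#' @export
#' @examples
#' calls <- tibble::tibble(sample = c("A", "B"), locus = "L1",
#'                         presence_score = c(6, 10))
#' encode_profiles(calls, bin_width = 2)
encode_profiles <- function(calls, bin_width = 1) {
  stopifnot(all(c("sample", "locus", "presence_score") %in% names(calls)))
  k <- 10 / bin_width
  if (bin_width <= 0 || bin_width > 10 || abs(k - round(k)) > 1e-9) {
    abort("bin_width must divide 10 evenly", class = "tedose_configuration")
  }
  k <- as.integer(round(k))
  samples <- unique(calls$sample)
  loci <- sort(unique(calls$locus))
  thresholds <- seq_len(k) * bin_width
  enc <- matrix(
    0L, nrow = length(samples), ncol = length(loci) * k,
    dimnames = list(samples, paste(rep(loci, each = k),
                                   rep(thresholds, length(loci)),
                                   sep = ":"))
  )
  for (r in seq_len(nrow(calls))) {
    s <- calls$sample[r]
    l <- match(calls$locus[r], loci)
    score <- calls$presence_score[r]
    if (is.na(score)) next
    block <- (l - 1L) * k + seq_len(k)
    enc[s, block] <- as.integer(score >= thresholds - 1e-9)
  }
  attr(enc, "loci") <- loci
  attr(enc, "bin_width") <- bin_width
  enc
}

#' Nei-Li (Dice) distance between binary profiles
#'
#' `D = 1 - 2 n_ab / (n_a + n_b)`, where `n_ab` counts shared 1-bands and
#' `n_a`, `n_b` the bands of each profile. Symmetric, 0 for identical
#' encodings, 1 for disjoint ones; the triangle inequality is not
#' guaranteed (Dice-based distances are semimetrics). The distance is
#' undefined between two all-zero profiles; all-zero samples are excluded
#' with a warning when a whole matrix is processed.
#'
#' @param x A 0/1 encoding matrix (samples in rows, see
#'   [encode_profiles()]) or a single 0/1 vector.
#' @param y Second vector when `x` is a vector.
#' @returns A [stats::dist] object (matrix input) or a scalar (vectors).
#' @export
#' @examples
#' nei_li_dist(c(1, 1, 1, 0), c(1, 1, 0, 0))  # 1 - 4/5 = 0.2
nei_li_dist <- function(x, y = NULL) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    na <- sum(x != 0)
    nb <- sum(y != 0)
    if (na + nb == 0) {
      abort("Nei-Li distance undefined for two all-zero profiles",
            class = "tedose_undefined_distance")
    }
    return(1 - 2 * sum(x != 0 & y != 0) / (na + nb))
  }
  stopifnot(is.matrix(x))
  zero <- rowSums(x != 0) == 0
  if (any(zero)) {
    warn(paste0("excluding all-zero profile(s): ",
                paste(rownames(x)[zero], collapse = ", ")))
    x <- x[!zero, , drop = FALSE]
  }
  if (nrow(x) < 2) {
    abort("need at least two non-empty profiles",
          class = "tedose_undefined_distance")
  }
  m <- (x != 0) * 1L
  shared <- m %*% t(m)
  counts <- rowSums(m)
  tot <- outer(counts, counts, "+")
  d <- 1 - 2 * shared / tot
  diag(d) <- 0
  stats::as.dist(d)
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group method with arithmetic mean: the closest
#' pair of clusters is merged, the new node is placed at half the merge
#' distance, and distances to the merged cluster are size-weighted
#' arithmetic means of the members' distances. Ties on the minimum distance
#' are broken by the lowest (row, column) index pair, so the output is
#' fully deterministic. The result is an ultrametric dendrogram.
#'
#' @param d A [stats::dist] object or symmetric matrix with zero diagonal.
#' @returns An ultrametric tree of class `c("tedose_dendrogram", "phylo")`
#'   with branch lengths; node heights (half merge distances) are attached
#'   as attribute `"heights"` and the merge table as attribute `"merges"`.
#' @export
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- upgma(d)
#' attr(tr, "merges")
upgma <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 2) {
    abort("need at least two samples", class = "tedose_malformed_input")
  }
  if (!isSymmetric(unname(dm)) || any(abs(diag(dm)) > 1e-12)) {
    abort("distance matrix must be symmetric with zero diagonal",
          class = "tedose_malformed_input")
  }
  n <- nrow(dm)
  labels <- rownames(dm) %||% paste0("t", seq_len(n))

  # active clusters: id (leaf 1..n, internal n+merge), members, size, height
  ids <- seq_len(n)
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  members <- as.list(seq_len(n))
  merges <- vector("list", n - 1)
  node_children <- vector("list", n - 1)
  node_height <- numeric(n - 1)
  clade <- vector("list", n - 1)

  for (m in seq_len(n - 1)) {
    k <- nrow(dm)
    best_i <- 1L; best_j <- 2L; best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (dm[i, j] < best_d) {
          best_d <- dm[i, j]; best_i <- i; best_j <- j
        }
      }
    }
    i <- best_i; j <- best_j
    h <- best_d / 2
    node_children[[m]] <- c(ids[i], ids[j])
    node_height[m] <- h
    clade[[m]] <- sort(c(members[[i]], members[[j]]))
    merges[[m]] <- tibble(step = m, merge_distance = best_d, height = h)

    new_row <- (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) / (sizes[i] + sizes[j])
    dm[i, ] <- new_row
    dm[, i] <- new_row
    dm[i, i] <- 0
    ids[i] <- n + m
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    members[[i]] <- clade[[m]]
    dm <- dm[-j, -j, drop = FALSE]
    ids <- ids[-j]; sizes <- sizes[-j]; heights <- heights[-j]
    members[j] <- NULL
  }

  # build the phylo edge table; internal node m -> 2n - m (root = n + 1)
  node_id <- function(x) if (x <= n) x else 2L * n - (x - n)
  all_heights <- c(rep(0, n), rep(NA_real_, n - 1))
  edges <- matrix(0L, 2 * (n - 1), 2)
  lens <- numeric(2 * (n - 1))
  e <- 0L
  for (m in seq_len(n - 1)) {
    parent <- node_id(n + m)
    all_heights[parent] <- node_height[m]
    for (child_raw in node_children[[m]]) {
      child <- node_id(child_raw)
      ch <- if (child_raw <= n) 0 else node_height[child_raw - n]
      e <- e + 1L
      edges[e, ] <- c(parent, child)
      lens[e] <- node_height[m] - ch
    }
  }
  tree <- structure(
    list(edge = edges, edge.length = lens, tip.label = labels,
         Nnode = n - 1L),
    class = c("tedose_dendrogram", "phylo")
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "heights") <- all_heights
  attr(tree, "merges") <- dplyr::bind_rows(merges)
  attr(tree, "clades") <- lapply(clade, function(ix) sort(labels[ix]))
  attr(tree, "clade_nodes") <- vapply(seq_len(n - 1),
                                      function(m) node_id(n + m), 0L)
  tree
}

clade_keys <- function(tree) {
  vapply(attr(tree, "clades"), paste, "", collapse = "\r")
}

# Dice distance that tolerates all-zero rows (used inside bootstrap
# resampling, where a resample can zero out a profile): two empty profiles
# are identical (0), an empty vs non-empty profile is disjoint (1).
dice_dist_safe <- function(m) {
  m <- (m != 0) * 1L
  counts <- rowSums(m)
  shared <- m %*% t(m)
  tot <- outer(counts, counts, "+")
  d <- ifelse(tot == 0, 0, 1 - 2 * shared / tot)
  diag(d) <- 0
  stats::as.dist(d)
}

#' UPGMA tree with bootstrap support over loci
#'
#' Builds the reference UPGMA tree from the full encoding, then resamples
#' loci with replacement `B` times, re-encodes, re-clusters, and scores
#' every internal node (except the root) by the percentage of replicate
#' trees containing the same leaf clade. Deterministic given `seed`.
#'
#' @param calls Dosage call table from [call_dosage()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the locus resampling.
#' @param bin_width Encoding bin width (see [encode_profiles()]).
#' @returns The reference `tedose_dendrogram` with `node.label` carrying
#'   percent support (root blank) and a tibble of per-node support as
#'   attribute `"support"`. With a single locus support is undefined and
#'   reported as `NA`.
#' @export
bootstrap_support <- function(calls, B = 100, seed = 1, bin_width = 1) {
  stopifnot(B >= 1)
  enc <- encode_profiles(calls, bin_width = bin_width)
  loci <- attr(enc, "loci")
  k <- ncol(enc) / length(loci)
  ref <- upgma(nei_li_dist(enc))

  n <- length(ref$tip.label)
  keys <- clade_keys(ref)
  root_idx <- which(vapply(attr(ref, "clades"), length, 0L) == n)

  if (length(loci) < 2) {
    support <- rep(NA_real_, n - 1)
  } else {
    counts <- numeric(n - 1)
    withr::with_seed(seed, {
      for (b in seq_len(B)) {
        pick <- sample(length(loci), replace = TRUE)
        cols <- as.vector(vapply(pick, function(l) (l - 1) * k + seq_len(k),
                                 numeric(k)))
        enc_b <- enc[, cols, drop = FALSE]
        tr_b <- upgma(dice_dist_safe(enc_b))
        counts <- counts + (keys %in% clade_keys(tr_b))
      }
    })
    support <- 100 * counts / B
  }
  support[root_idx] <- NA_real_

  support_tbl <- tibble(
    node = attr(ref, "clade_nodes"),
    height = vapply(seq_len(n - 1), function(m) attr(ref, "merges")$height[m], 0),
    n_leaves = vapply(attr(ref, "clades"), length, 0L),
    support = support
  )
  # node.label ordered by internal node number n+1 .. 2n-1
  lab <- rep("", n - 1)
  lab[support_tbl$node - n] <- ifelse(is.na(support_tbl$support), "",
                                      format(round(support_tbl$support, 1)))
  ref$node.label <- lab
  attr(ref, "support") <- support_tbl
  ref
}

#' Write a dendrogram to Newick
#'
#' @param tree A `tedose_dendrogram` (or any `phylo`) object.
#' @param file Output path.
#' @returns The file path, invisibly.
#' @export
write_dendrogram <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}
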