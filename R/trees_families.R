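#' Neighbor-joining tree from a genetic distance matrix
#'
#' Saitou-Nei neighbor joining: repeatedly join the pair minimizing
#' `Q_ij = (n - 2) d_ij - r_i - r_j` (with `r` the row sums), with branch
#' lengths from the standard three-point formulas. Ties are broken toward
#' the smallest (i, j) index pair in the current matrix. Negative branch
#' estimates are clamped to zero with the deficit moved to the sister
#' branch, so the path length between the joined taxa is preserved. The
#' result is an unrooted tree (trifurcating root node for > 2 taxa),
#' returned as an [ape::phylo] object serializable to Newick with
#' [ape::write.tree()].
#'
#' @param distance a [kinship_matrix()] of flavor `"IBS_distance"`, or any
#'   symmetric zero-diagonal distance matrix with sample-id dimnames.
#' @return An `ape` `phylo` tree whose tip labels are the sample ids.
#' @export
nj_tree <- function(distance) {
  D <- unclass(distance)
  attr(D, "flavor") <- NULL
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 2) stop("need at least two taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  clamp2 <- function(bi, bj) {
    # keep bi + bj, move any deficit to the sister branch
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  nwk <- labs
  while (length(nwk) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- t(apply(best, 1, sort))
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    b <- clamp2(bi, bj)
    new_nwk <- paste0("(", nwk[i], ":", fmt(b[1]), ",", nwk[j], ":",
                      fmt(b[2]), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
  }
  if (length(nwk) == 2) {
    b <- D[1, 2] / 2
    s <- paste0("(", nwk[1], ":", fmt(b), ",", nwk[2], ":", fmt(b), ");")
  } else {
    b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    s <- paste0("(", nwk[1], ":", fmt(b1), ",", nwk[2], ":", fmt(b2), ",",
                nwk[3], ":", fmt(b3), ");")
  }
  ape::read.tree(text = s)
}

#' Cluster males into families by a kinship threshold
#'
#' Builds a graph over the male samples with an edge wherever pairwise
#' genomic kinship reaches `threshold`; the connected components (i.e.
#' transitive closure of the relatedness relation) are the sire families.
#' Components are ordered by their earliest member in `male_ids`.
#'
#' @param G a [kinship_matrix()] of flavor `"G"` (or any symmetric kinship
#'   matrix with id dimnames).
#' @param male_ids ids of the male samples.
#' @param threshold kinship cutoff (default 0.1).
#' @return A list of character vectors, one per family.
#' @export
cluster_males <- function(G, male_ids, threshold = 0.1) {
  stopifnot(length(male_ids) >= 1)
  idx <- match(male_ids, rownames(G))
  if (anyNA(idx)) stop("male id(s) missing from kinship matrix")
  A <- unclass(G)[idx, idx, drop = FALSE] >= threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  fams <- split(male_ids, comp)
  fams <- fams[order(vapply(fams, function(f)
    min(match(f, male_ids)), numeric(1)))]
  names(fams) <- NULL
  fams
}

#' Assign females to male-anchored families
#'
#' A female's kinship to a family is her maximum kinship over that family's
#' males. She joins the family with the largest such kinship provided it
#' reaches `threshold` (ties resolved toward the lowest family id);
#' otherwise she falls in the `"other"` class of animals with no close male
#' relative.
#'
#' @param G kinship matrix with id dimnames.
#' @param male_families list of male-id vectors from [cluster_males()].
#' @param female_ids ids of the female samples.
#' @param threshold kinship cutoff (default 0.1).
#' @return A list of class `family_assignment`: `families` (list of
#'   `list(id, males, females)`), `other` (female ids) and `threshold`.
#' @export
assign_females <- function(G, male_families, female_ids, threshold = 0.1) {
  Gm <- unclass(G)
  fam_females <- vector("list", length(male_families))
  other <- character(0)
  for (f in female_ids) {
    if (!f %in% rownames(Gm)) stop("female id missing from kinship matrix: ", f)
    kin <- vapply(male_families, function(males)
      max(Gm[f, males]), numeric(1))
    best <- which.max(kin)   # first maximum = lowest family id on ties
    if (length(kin) && kin[best] >= threshold)
      fam_females[[best]] <- c(fam_females[[best]], f)
    else
      other <- c(other, f)
  }
  families <- lapply(seq_along(male_families), function(k)
    list(id = k, males = male_families[[k]],
         females = if (is.null(fam_females[[k]])) character(0)
                   else fam_females[[k]]))
  structure(list(families = families, other = other, threshold = threshold),
            class = "family_assignment")
}

#' Partition a population into sire families
#'
#' Convenience wrapper: clusters the males of `gm` with [cluster_males()]
#' and assigns the females with [assign_females()], both at the same
#' kinship threshold.
#'
#' @param G kinship matrix (flavor `"G"`).
#' @param gm the [genotype_matrix()] the kinship was computed from (supplies
#'   sample sexes).
#' @param threshold kinship cutoff (default 0.1).
#' @return A `family_assignment`.
#' @export
build_families <- function(G, gm, threshold = 0.1) {
  males <- gm$samples$id[gm$samples$sex == "male"]
  females <- gm$samples$id[gm$samples$sex == "female"]
  if (!length(males)) stop("family construction needs at least one male")
  assign_females(G, cluster_males(G, males, threshold), females, threshold)
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("Family partition (kinship threshold ", x$threshold, ")\n", sep = "")
  for (f in x$families)
    cat("  Family ", f$id, ": males [",
        paste(f$males, collapse = ", "), "], females [",
        paste(f$females, collapse = ", "), "]\n", sep = "")
  cat("  Other: ", length(x$other), " females\n", sep = "")
  invisible(x)
}

#' Tidy a family assignment into a long table
#'
#' @param fa a `family_assignment`.
#' @return A data.frame with columns `family` (`"other"` for unassigned
#'   females), `id` and `sex_role` (`"male"`/`"female"`).
#' @export
family_table <- function(fa) {
  stopifnot(inherits(fa, "family_assignment"))
  rows <- list()
  for (f in fa$families) {
    if (length(f$males))
      rows[[length(rows) + 1L]] <- data.frame(
        family = as.character(f$id), id = f$males, sex_role = "male",
        stringsAsFactors = FALSE)
    if (length(f$females))
      rows[[length(rows) + 1L]] <- data.frame(
        family = as.character(f$id), id = f$females, sex_role = "female",
        stringsAsFactors = FALSE)
  }
  if (length(fa$other))
    rows[[length(rows) + 1L]] <- data.frame(
      family = "other", id = fa$other, sex_role = "female",
      stringsAsFactors = FALSE)
  if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), id = character(0),
               sex_role = character(0), stringsAsFactors = FALSE)
}
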