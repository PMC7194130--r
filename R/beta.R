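# Sorensen-family beta-diversity partitioning into species turnover and
# nestedness-resultant dissimilarity.
#
# Pairwise, for sites 1 and 2 with a shared species, b unique to site 1 and
# c unique to site 2:
#
#   bsor = (b + c) / (2a + b + c)                total dissimilarity
#   bsim = min(b, c) / (a + min(b, c))           turnover (replacement)
#   bsne = bsor - bsim                           nestedness-resultant
#        = (max - min) / (2a + b + c) * a / (a + min)
#
# The multiple-site forms generalize these via the sums of one-sided
# unique-species counts over all site pairs.  All computations are
# incidence-based; cover matrices are thresholded at > 0 first.

#' Shared and unique species counts for a site pair
#'
#' @param site1,site2 Incidence (0/1 or logical) vectors over the same
#'   species list.
#' @return List of class `pair_counts` with `a` (shared), `b` (only in
#'   `site1`), `c` (only in `site2`).
#' @export
#' @examples
#' pair_counts(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 1))
pair_counts <- function(site1, site2) {
  .assert(length(site1) == length(site2),
          "sites must share the same species list")
  s1 <- as.logical(site1); s2 <- as.logical(site2)
  .assert(!anyNA(s1) && !anyNA(s2), "incidence vectors must be 0/1")
  out <- list(a = sum(s1 & s2), b = sum(s1 & !s2), c = sum(!s1 & s2))
  .assert(out$a + out$b >= 1 && out$a + out$c >= 1,
          "cannot compare empty sites")
  class(out) <- "pair_counts"
  out
}

#' Partition pairwise Sorensen dissimilarity
#'
#' @param counts A [pair_counts()] object, or a numeric vector/list with
#'   elements `a`, `b`, `c`.
#' @return Object of class `beta_partition`: list with `bsor`, `bsim`,
#'   `bsne` (all in \[0, 1\], with `bsor = bsim + bsne`).
#' @export
#' @examples
#' pairwise_partition(list(a = 2, b = 2, c = 1))
pairwise_partition <- function(counts) {
  a <- counts[["a"]]; b <- counts[["b"]]; cc <- counts[["c"]]
  .assert(all(c(a, b, cc) >= 0) && all(c(a, b, cc) == round(c(a, b, cc))),
          "counts must be non-negative integers")
  .assert(2 * a + b + cc > 0, "undefined for two empty sites")
  .assert(a + b >= 1 && a + cc >= 1,
          "dissimilarity undefined when one site is empty")
  m <- min(b, cc)
  bsor <- (b + cc) / (2 * a + b + cc)
  bsim <- if (a + m == 0) 0 else m / (a + m)   # a>0, m=0 -> 0; a=0, m>0 -> 1
  structure(list(bsor = bsor, bsim = bsim, bsne = bsor - bsim),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("beta partition: bsor = %.4f = bsim %.4f + bsne %.4f\n",
              x$bsor, x$bsim, x$bsne))
  invisible(x)
}

#' Multiple-site Sorensen partition
#'
#' Generalizes the pairwise partition to n sites.  With `Si` the richness
#' of site i, `ST` the pooled richness, and `bij`, `bji` the one-sided
#' unique-species counts of each pair, the turnover component is
#' `sum(min) / (sum(Si) - ST + sum(min))`, the total dissimilarity is
#' `(sum(min) + sum(max)) / (2 (sum(Si) - ST) + sum(min) + sum(max))`, and
#' the nestedness-resultant component is their difference.  For n = 2 this
#' reduces exactly to [pairwise_partition()].
#'
#' @param m Incidence matrix (sites x species), a `community_matrix`, or a
#'   cover matrix (thresholded at > 0).
#' @return A `beta_partition` with an `n_sites` attribute.
#' @export
multisite_partition <- function(m) {
  inc <- .incidence(m)
  .assert(nrow(inc) >= 2, "need at least 2 sites")
  empty <- rowSums(inc) == 0
  .assert(!any(empty), "empty site(s): ",
          paste(rownames(inc)[empty] %||% which(empty), collapse = ", "))
  Si <- rowSums(inc)
  ST <- sum(colSums(inc) > 0)
  shared <- tcrossprod(inc)              # a_ij
  uniq <- Si - shared                    # b_ij = species in i not in j
  ut <- upper.tri(uniq)
  bij <- uniq[ut]; bji <- t(uniq)[ut]
  sum_min <- sum(pmin(bij, bji))
  sum_max <- sum(pmax(bij, bji))
  asum <- sum(Si) - ST
  bsim <- if (asum + sum_min == 0) 0 else sum_min / (asum + sum_min)
  denom <- 2 * asum + sum_min + sum_max
  bsor <- if (denom == 0) 0 else (sum_min + sum_max) / denom
  out <- structure(list(bsor = bsor, bsim = bsim, bsne = bsor - bsim),
                   class = "beta_partition")
  attr(out, "n_sites") <- nrow(inc)
  out
}

#' Temporal partition: site-wise dissimilarity between two surveys
#'
#' Matches sites between the baseline and resurvey matrices on their
#' metadata (everything except year) and computes the pairwise partition
#' of each site against itself through time.  A site losing species with
#' no gains has `bsim = 0` (pure nestedness through time); a site swapping
#' equal numbers has `bsne = 0` (pure turnover).
#'
#' @param m1,m2 `community_matrix` objects (baseline, resurvey) built at
#'   the same grouping, or plain incidence matrices with matching
#'   rownames.
#' @return data.frame with one row per matched site: the counts `a`, `b`,
#'   `c` and components `bsor`, `bsim`, `bsne`.
#' @export
temporal_partition <- function(m1, m2) {
  site_key <- function(m) {
    if (inherits(m, "community_matrix")) {
      meta <- m$sites[setdiff(names(m$sites), c("site", "year", "elevation"))]
      do.call(paste, c(meta, sep = "."))
    } else {
      rownames(as.matrix(m)) %||% .stop("matrices need rownames")
    }
  }
  k1 <- site_key(m1); k2 <- site_key(m2)
  orphans <- c(setdiff(k1, k2), setdiff(k2, k1))
  .assert(length(orphans) == 0L,
          "unmatched site(s) between years: ",
          paste(orphans, collapse = ", "))
  v1 <- .incidence(m1); v2 <- .incidence(m2)
  sp <- sort(union(colnames(v1) %||% as.character(seq_len(ncol(v1))),
                   colnames(v2) %||% as.character(seq_len(ncol(v2)))))
  expand <- function(v) {
    out <- matrix(0, nrow(v), length(sp), dimnames = list(NULL, sp))
    out[, colnames(v) %||% sp[seq_len(ncol(v))]] <- v
    out
  }
  v1 <- expand(v1); v2 <- expand(v2)
  rows <- lapply(seq_along(k1), function(i) {
    j <- match(k1[i], k2)
    pc <- pair_counts(v1[i, ], v2[j, ])
    bp <- pairwise_partition(pc)
    data.frame(site = k1[i], a = pc$a, b = pc$b, c = pc$c,
               bsor = bp$bsor, bsim = bp$bsim, bsne = bp$bsne,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$site), , drop = FALSE]
}

#' Pairwise dissimilarity matrix for one partition component
#'
#' @param m Incidence (or cover) matrix or `community_matrix`.
#' @param component `"bsor"`, `"bsim"`, or `"bsne"`.
#' @return Square symmetric matrix with zero diagonal and site labels.
#' @export
component_distance_matrix <- function(m,
                                      component = c("bsor", "bsim", "bsne")) {
  component <- match.arg(component)
  inc <- .incidence(m)
  .assert(nrow(inc) >= 2, "need at least 2 sites")
  labs <- rownames(inc) %||% as.character(seq_len(nrow(inc)))
  n <- nrow(inc)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bp <- pairwise_partition(pair_counts(inc[i, ], inc[j, ]))
      d[i, j] <- d[j, i] <- bp[[component]]
    }
  }
  d
}

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' Sites are ordered lexicographically by label before agglomeration so
#' that ties are broken deterministically.
#'
#' @param d Square symmetric non-negative matrix with zero diagonal (or a
#'   `dist`).
#' @return An `hclust` object (method "average").
#' @export
average_linkage_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    .assert(nrow(d) == ncol(d) && isTRUE(all.equal(d, t(d))),
            "dissimilarity matrix must be square and symmetric")
    .assert(all(diag(d) == 0) && all(d >= 0),
            "dissimilarity matrix must be non-negative with zero diagonal")
    labs <- rownames(d) %||% as.character(seq_len(nrow(d)))
    o <- order(labs)
    d <- stats::as.dist(d[o, o])
  }
  stats::hclust(d, method = "average")
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths carry the UPGMA merge heights.
#'
#' @param hc An `hclust` (e.g. from [average_linkage_cluster()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  .assert(inherits(hc, "hclust"), "'hc' must be an hclust object")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
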