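# Independent oracles and small fixture builders shared across tests.

# Brute-force O(n^2) DBSCAN: full pairwise adjacency, BFS expansion from
# core points.  Kept deliberately naive and independent of the package's
# sorted-sweep implementation.
oracle_dbscan <- function(d, eps, min_pts) {
  n <- length(d)
  adj <- abs(outer(d, d, "-")) <= eps
  core <- rowSums(adj) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0L) {
      j <- queue[1]
      queue <- queue[-1]
      for (q in which(adj[j, ])) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  list(kept = d[labels > 0L], removed = d[labels == 0L])
}

# closed-form single-Gaussian MLE (mean, biased variance, log-likelihood)
oracle_gauss_mle <- function(d) {
  mu <- mean(d)
  v <- mean((d - mu)^2)
  list(mean = mu, var = v,
       loglik = sum(dnorm(d, mu, sqrt(v), log = TRUE)))
}

# random 1-D DBSCAN instance: mixture of clumps plus stragglers
random_dbscan_instance <- function() {
  n_clumps <- sample(1:3, 1)
  d <- unlist(lapply(seq_len(n_clumps), function(i) {
    rnorm(sample(5:60, 1), mean = runif(1, 0, 50000), sd = runif(1, 10, 500))
  }))
  d <- c(d, runif(sample(0:8, 1), 0, 60000))
  d <- d[seq_len(min(length(d), 200))]
  list(d = d,
       eps = runif(1, 50, 5000),
       min_pts = sample(3:8, 1))
}

expect_same_multiset <- function(a, b) {
  expect_equal(sort(a), sort(b))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# a small CMAP fixture body with the standard header
cmap_fixture_lines <- function(rows) {
  c("# CMAP File Version:\t0.1",
    "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition",
    rows)
}

xmap_fixture_lines <- function(rows) {
  c("# XMAP File Version:\t0.2",
    "#h XmapEntryID\tQryContigID\tRefContigID\tOrientation\tConfidence\tAlignment",
    rows)
}

# a reference label map and one aligned molecule, built in code
make_label_map <- function(map_id, site_ids, positions,
                           length_bp = max(positions) + 1000) {
  structure(list(map_id = as.character(map_id),
                 positions = data.frame(site_id = as.integer(site_ids),
                                        position_bp = as.numeric(positions)),
                 length_bp = length_bp),
            class = "label_map")
}

make_alignment <- function(molecule_id, ref_contig_id, pairs,
                           orientation = "+", confidence = 20) {
  m <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("ref_site", "qry_site")))
  structure(list(molecule_id = as.character(molecule_id),
                 ref_contig_id = as.character(ref_contig_id),
                 orientation = orientation,
                 confidence = confidence,
                 pairs = m),
            class = "molecule_alignment")
}

# minimal hand-built mixture_fit for select_model tests
fake_fit <- function(k, bic, weights) {
  structure(list(k = as.integer(k),
                 components = data.frame(mean_bp = seq_len(k) * 1000,
                                         sd_bp = rep(100, k),
                                         weight = weights),
                 loglik = 0, bic = bic, n = 100L, converged = TRUE),
            class = "mixture_fit")
}
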