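# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk.

# quick mcc_data from a numeric matrix (all-numerical features)
numeric_mcc_data <- function(X, group = "questionnaire", ids = NULL) {
  cn <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  cn[cn == ""] <- paste0("f", which(cn == ""))
  colnames(X) <- cn
  tab <- tibble::as_tibble(as.data.frame(X))
  tab <- tibble::add_column(
    tab, subject_id = ids %||% sprintf("S%03d", seq_len(nrow(X))), .before = 1)
  mcc_data(tab, feature_spec(colnames(X), "numerical", group = group))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# planted three-view mixed-type recovery fixture: 134 subjects, 200 features,
# between-cluster mean gaps of 3 sd, 10% missing entries
make_recovery_fixture <- function(seed) recovery_fixture(seed)

# view-partition ARI and the worst per-view subject ARI of a fitted solution
# against the planted truth (views matched by feature overlap)
recovery_agreement <- function(fit, fixture) {
  fa <- fit$feature_assignments
  plan <- fixture$plan
  view_ari <- adjusted_rand_index(fa$view[match(plan$feature, fa$feature)],
                                  plan$view)
  subj <- vapply(sort(unique(plan$view)), function(v) {
    feats <- plan$feature[plan$view == v]
    mv <- as.integer(names(which.max(table(fa$view[match(feats, fa$feature)]))))
    sv <- fit$subject_assignments[fit$subject_assignments$view == mv, ]
    adjusted_rand_index(sv$cluster[order(sv$subject_id)],
                        fixture[[paste0("p", v)]])
  }, 0.0)
  list(view_ari = view_ari, subject_ari = min(subj))
}

# the fixed small matrix for the exhaustive-enumeration oracle: two tight
# subject clusters (rows 1-3 vs 4-6) on f1/f2 and a different tight
# partition (rows 1-2 vs 3-6) on f3/f4
small_oracle_matrix <- function() {
  rbind(c( 3.0,  3.1,  2.0,  2.1),
        c( 2.9,  3.0,  1.9,  2.0),
        c( 3.1,  2.9, -2.0, -2.1),
        c(-3.0, -3.1, -1.9, -2.0),
        c(-2.9, -3.0, -2.1, -1.9),
        c(-3.1, -2.9, -2.0, -2.0))
}

# Independent brute-force oracle: maximum plug-in log-likelihood over every
# hard assignment of 4 features to (view, feature-cluster) pairs and 6
# subjects to clusters, truncation (2, 2, 2), under the default priors.
# Written from the conjugate closed forms directly; shares no code with the
# package's fitting path.
oracle_max_plugin_loglik <- function(X) {
  lambda0 <- 1 / 100; mu0 <- 0; gamma0 <- 1 / 100; sigma0_sq <- 1 / 100
  block_ll <- function(xs) {
    n <- length(xs)
    if (n == 0) return(0)
    lam <- lambda0 + n
    mu <- (lambda0 * mu0 + sum(xs)) / lam
    shape <- gamma0 / 2 + n / 2
    rate <- gamma0 * sigma0_sq / 2 +
      0.5 * (sum(xs^2) + lambda0 * mu0^2 - lam * mu^2)
    prec <- shape / rate
    0.5 * n * (log(prec) - log(2 * pi)) - 0.5 * prec * sum((xs - mu)^2)
  }
  subj <- as.matrix(expand.grid(rep(list(1:2), nrow(X))))
  feat <- as.matrix(expand.grid(rep(list(1:4), ncol(X))))
  best <- -Inf
  for (fi in seq_len(nrow(feat))) {
    fa <- feat[fi, ]
    v_of <- (fa - 1) %/% 2 + 1
    g_of <- (fa - 1) %% 2 + 1
    tot <- 0
    for (v in 1:2) {
      js <- which(v_of == v)
      if (length(js) == 0) next
      bestv <- -Inf
      for (si in seq_len(nrow(subj))) {
        k <- subj[si, ]
        ll <- 0
        for (g in unique(g_of[js])) {
          cols <- js[g_of[js] == g]
          for (kk in unique(k)) {
            ll <- ll + block_ll(as.vector(X[k == kk, cols, drop = FALSE]))
          }
        }
        if (ll > bestv) bestv <- ll
      }
      tot <- tot + bestv
    }
    if (tot > best) best <- tot
  }
  best
}

# brute-force adjusted Rand index by explicit pair enumeration
ari_pair_counting <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  np <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / np
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, mx) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(mx + 1L)) grow(c(labels, l), max(mx, l))
  }
  grow(integer(0), 0L)
  out
}
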