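# Independent brute-force oracles used to cross-check the implementation.
# They work on dense logical adjacency matrices and plain loops, deliberately
# sharing no code with the package internals.

random_edge_tbl <- function(n, p) {
  v <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(v, 2)
  keep <- stats::runif(ncol(pairs)) < p
  tibble::tibble(from = pairs[1, keep], to = pairs[2, keep])
}

oracle_adj <- function(edges, vertices = NULL) {
  v <- sort(unique(c(edges$from, edges$to, vertices)))
  A <- matrix(FALSE, length(v), length(v), dimnames = list(v, v))
  for (k in seq_len(nrow(edges))) {
    A[edges$from[k], edges$to[k]] <- TRUE
    A[edges$to[k], edges$from[k]] <- TRUE
  }
  A
}

oracle_jcs <- function(A, v, u) {
  cn <- sum(A[v, ] & A[u, ])
  if (cn < 1) return(0)
  cn / sum(A[v, ] | A[u, ])
}

oracle_cns <- function(A, v, u) {
  cn <- colnames(A)[A[v, ] & A[u, ]]
  s <- 0
  for (w in cn) s <- s + oracle_jcs(A, v, w) * oracle_jcs(A, w, u)
  s
}

oracle_hocn <- function(A, v, u) {
  cn <- sum(A[v, ] & A[u, ])
  if (cn < 1) return(NA_real_)
  (oracle_jcs(A, v, u) + oracle_cns(A, v, u)) / (cn + 1)
}

# Weighted network as a data frame (from < to) of retained edges.
oracle_weight_network <- function(edges) {
  A <- oracle_adj(edges)
  out <- list()
  for (k in seq_len(nrow(edges))) {
    a <- min(edges$from[k], edges$to[k])
    b <- max(edges$from[k], edges$to[k])
    w <- oracle_hocn(A, a, b)
    if (!is.na(w)) out[[length(out) + 1]] <- data.frame(from = a, to = b,
                                                       hocn = w)
  }
  if (!length(out)) {
    return(data.frame(from = character(), to = character(), hocn = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$from, df$to), , drop = FALSE]
}

oracle_ss <- function(A, v, w) {
  S <- A
  diag(S) <- TRUE
  sum(S[v, ] & S[w, ]) / sqrt(sum(S[v, ]) * sum(S[w, ]))
}

# Weight matrix of the filtered network (0 for non-edges).
oracle_weight_matrix <- function(wdf, vertices) {
  W <- matrix(0, length(vertices), length(vertices),
              dimnames = list(vertices, vertices))
  for (k in seq_len(nrow(wdf))) {
    W[wdf$from[k], wdf$to[k]] <- wdf$hocn[k]
    W[wdf$to[k], wdf$from[k]] <- wdf$hocn[k]
  }
  W
}

# CAP and role classification for one core (member-name vector).
oracle_attach_one <- function(W, core) {
  v <- rownames(W)
  A <- W > 0
  outside <- setdiff(v, core)
  cap <- outside[vapply(outside, function(p) sum(A[p, core]) >= 2, logical(1))]
  w_in <- vapply(cap, function(p) sum(W[p, core]), numeric(1))
  w_out <- vapply(cap, function(p) sum(W[p, setdiff(v, core)]), numeric(1))
  wavg <- sum(W[core, core]) / length(core) # each internal edge counted twice
  ovl <- cap[w_out >= w_in & w_in >= wavg / 2]
  cp <- setdiff(cap, ovl)
  per <- character()
  if (length(cp)) {
    cpm <- mean(w_in[cp])
    per <- cp[w_in[cp] > w_out[cp] & w_in[cp] >= cpm]
  }
  list(cap = cap, w_in = w_in, w_out = w_out, weight_avg = wavg,
       overlapping = ovl, peripheral = per)
}

oracle_na <- function(a, b) length(intersect(a, b))^2 / (length(a) * length(b))

oracle_metrics <- function(pred, ref, t) {
  nmr <- 0
  for (r in ref) {
    if (any(vapply(pred, function(p) oracle_na(r, p) >= t, logical(1)))) {
      nmr <- nmr + 1
    }
  }
  nmp <- 0
  for (p in pred) {
    if (any(vapply(ref, function(r) oracle_na(p, r) >= t, logical(1)))) {
      nmp <- nmp + 1
    }
  }
  recall <- nmr / length(ref)
  precision <- if (length(pred)) nmp / length(pred) else 0
  f <- if (recall + precision > 0) 2 * precision * recall / (precision + recall) else 0
  cr <- sum(vapply(ref, function(r) {
    if (!length(pred)) return(0L)
    max(vapply(pred, function(p) length(intersect(r, p)), integer(1)))
  }, integer(1))) / sum(lengths(ref))
  list(recall = recall, precision = precision, f_measure = f, cr = cr)
}

# Exhaustive maximum-weight matching over an NA matrix (rows = ref).
oracle_mmr <- function(pred, ref, threshold = 0) {
  M <- matrix(0, length(ref), length(pred))
  for (i in seq_along(ref)) {
    for (j in seq_along(pred)) {
      na <- oracle_na(ref[[i]], pred[[j]])
      if (na > threshold) M[i, j] <- na
    }
  }
  best <- 0
  rec <- function(i, used, acc) {
    if (i > nrow(M)) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(i + 1, used, acc)
    for (j in seq_len(ncol(M))) {
      if (!used[j] && M[i, j] > 0) {
        used[j] <- TRUE
        rec(i + 1, used, acc + M[i, j])
        used[j] <- FALSE
      }
    }
  }
  if (ncol(M)) rec(1, logical(ncol(M)), 0)
  best / length(ref)
}

random_complex_set <- function(universe, k_max = 6) {
  k <- sample.int(k_max, 1)
  lapply(seq_len(k), function(i) {
    sample(universe, sample(2:5, 1))
  })
}

# Hypergeometric upper tail summed directly from log-binomials.
oracle_hyper_tail <- function(m, N, C, F) {
  if (m == 0) return(1)
  i <- m:min(C, F)
  sum(exp(lchoose(F, i) + lchoose(N - F, C - i) - lchoose(N, C)))
}
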