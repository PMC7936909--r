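# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: betweenness by exhaustive simple-path enumeration,
# hypergeometric tails by enumeration of all draws.

# Normalized betweenness by enumerating every simple path between every
# node pair and keeping the geodesics. adj is a 0/1 symmetric matrix.
enum_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  nb <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  all_simple <- function(s, t) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      for (w in nb[[v]]) if (!(w %in% path)) rec(c(path, w))
    }
    rec(s)
    res
  }
  raw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- all_simple(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, length, integer(1))
      geo <- ps[lens == min(lens)]
      sigma <- length(geo)
      interior <- unlist(lapply(geo, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tb <- table(interior)
        idx <- as.integer(names(tb))
        raw[idx] <- raw[idx] + as.numeric(tb) / sigma
      }
    }
  }
  raw * 2 / ((n - 1) * (n - 2))
}

# Build an igraph (plus its adjacency matrix) on n nodes from the bits of
# `code` over the n*(n-1)/2 possible edges; nodes named v1..vn.
graph_from_bits <- function(n, code) {
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(code))[seq_len(m)]
  adj <- matrix(0L, n, n)
  adj[lower.tri(adj)] <- bits
  adj <- adj + t(adj)
  ids <- paste0("v", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  ed <- which(lower.tri(adj) & adj > 0, arr.ind = TRUE)
  g <- netpharm::layered_graph(
    data.frame(id = ids, layer = "target", stringsAsFactors = FALSE),
    data.frame(from = ids[ed[, 2]], to = ids[ed[, 1]],
               kind = rep("ppi", nrow(ed)), stringsAsFactors = FALSE)
  )
  list(graph = g, adj = adj)
}

# Upper-tail hypergeometric probability by enumerating all C(N, n) draws,
# with genes 1..K marked.
enum_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Hand-rolled BH step-up used to cross-check bh_adjust.
stepup_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_along(ps)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

# Tiny two-group count matrix used by several DE tests.
toy_counts <- function(mat, n_a, n_b) {
  samples <- c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b)))
  colnames(mat) <- samples
  if (is.null(rownames(mat))) rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  netpharm::count_matrix(
    mat, stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)
  )
}
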