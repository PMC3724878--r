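# Shared toy networks and brute-force oracles. The oracles work directly on
# the node/edge tables with plain R loops, independently of the package's
# compiled dynamics engine.

toggle_net <- function() exampleToggleNetwork()

self_activator <- function() {
  thresholdNetwork(data.frame(name = "S"),
                   data.frame(source = "S", target = "S", strength = 1L))
}

# three-node ring: X -> Y -> Z -| X
ring_net <- function(theta_x = 0L) {
  thresholdNetwork(
    nodes = data.frame(name = c("X", "Y", "Z"),
                       threshold = c(theta_x, 0L, 0L)),
    edges = data.frame(source = c("X", "Y", "Z"),
                       target = c("Y", "Z", "X"),
                       strength = c(1L, 1L, -1L)))
}

# brute-force synchronous update straight off the tables
brute_step <- function(net, state) {
  nd <- nodeTable(net)
  ed <- edgeTable(net)
  out <- state
  for (i in seq_len(nrow(nd))) {
    if (nd$is_input[i]) next
    inc <- ed[ed$target == nd$name[i], , drop = FALSE]
    s <- if (nrow(inc)) sum(inc$strength * state[inc$source]) else 0L
    out[nd$name[i]] <- if (s > nd$threshold[i]) 1L else 0L
  }
  out
}

# brute-force trajectory -> list(cycle = list of states, transient = int)
brute_attractor <- function(net, state, maxit = 500L) {
  names(state) <- nodeNames(net)
  keys <- character()
  path <- list()
  for (t in 0:maxit) {
    k <- paste(state, collapse = "")
    hit <- match(k, keys)
    if (!is.na(hit))
      return(list(cycle = path[hit:length(path)], transient = hit - 1L))
    keys <- c(keys, k)
    path[[length(path) + 1L]] <- state
    state <- brute_step(net, state)
  }
  stop("no revisit within maxit")
}

# brute-force exhaustive basins over the free nodes -> named fractions where
# the name is a canonical cycle key (lexicographically smallest state first)
brute_basins <- function(net, maxit = 500L) {
  n <- nNodes(net)
  stopifnot(n <= 14)
  counts <- list()
  for (code in 0:(2^n - 1)) {
    state <- as.integer(intToBits(code))[seq_len(n)]
    res <- brute_attractor(net, state, maxit)
    strs <- vapply(res$cycle, paste, "", collapse = "")
    rot <- which.min(strs)
    key <- paste(strs[c(rot:length(strs), seq_len(rot - 1))], collapse = "|")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  unlist(counts) / 2^n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force betweenness on a directed graph (BFS shortest-path counting)
brute_betweenness <- function(net) {
  nm <- nodeNames(net)
  n <- length(nm)
  adj <- lapply(seq_len(n), function(i) integer())
  ed <- edgeTable(net)
  for (r in seq_len(nrow(ed))) {
    s <- match(ed$source[r], nm); t <- match(ed$target[r], nm)
    if (s != t) adj[[s]] <- c(adj[[s]], t)
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # Brandes-style accumulation
    dist <- rep(-1L, n); sigma <- numeric(n); preds <- lapply(1:n, function(i) integer())
    dist[s] <- 0L; sigma[s] <- 1
    queue <- c(s); order <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; order <- c(order, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  setNames(bc, nm)
}

builtin_markers <- function() markerConfig()
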