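# Median-joining network construction (Bandelt-style): iterated
# epsilon-relaxed minimum-spanning-network over the haplotypes, adding
# median (consensus) vectors of triples whenever they shorten the minimum
# spanning tree, then pruning median vectors that no longer serve as
# branching points.

hammingMatrix <- function(states) {
  H <- nrow(states)
  d <- matrix(0L, H, H)
  if (H < 2) return(d)
  for (i in seq_len(H - 1)) for (j in (i + 1):H)
    d[i, j] <- d[j, i] <- sum(states[i, ] != states[j, ])
  d
}

# Prim MST: returns edge matrix (i, j) and total length.
mstEdges <- function(d) {
  H <- nrow(d)
  if (H < 2) return(list(edges = matrix(0L, 0, 2), length = 0))
  inTree <- c(TRUE, rep(FALSE, H - 1))
  best <- d[1, ]; parent <- rep(1L, H)
  edges <- matrix(0L, H - 1, 2)
  total <- 0
  for (e in seq_len(H - 1)) {
    cand <- which(!inTree)
    v <- cand[which.min(best[cand])]
    edges[e, ] <- c(parent[v], v)
    total <- total + best[v]
    inTree[v] <- TRUE
    upd <- !inTree & d[v, ] < best
    best[upd] <- d[v, upd]
    parent[upd] <- v
  }
  list(edges = edges, length = total)
}

# Bottleneck (minimax) matrix from an MST: B[u,v] = largest edge weight on
# the unique MST path between u and v.
bottleneckMatrix <- function(d, mst) {
  H <- nrow(d)
  B <- matrix(0, H, H)
  adj <- vector("list", H)
  for (e in seq_len(nrow(mst$edges))) {
    i <- mst$edges[e, 1]; j <- mst$edges[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(H)) {
    seen <- rep(FALSE, H); seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (seen[v]) next
        seen[v] <- TRUE
        B[s, v] <- max(B[s, u], d[u, v])
        queue <- c(queue, v)
      }
    }
  }
  B
}

# epsilon-relaxed minimum spanning network link set.
msnLinks <- function(d, epsilon) {
  mst <- mstEdges(d)
  B <- bottleneckMatrix(d, mst)
  H <- nrow(d)
  links <- which(upper.tri(d) & d <= B + epsilon & d > 0, arr.ind = TRUE)
  links
}

siteMedian <- function(a, b, c) {
  out <- a
  for (s in seq_along(a)) {
    v <- c(a[s], b[s], c[s])
    tb <- table(v)
    if (max(tb) == 1L) return(NULL)  # all three distinct: no median
    out[s] <- names(tb)[which.max(tb)]
  }
  out
}

#' Median-joining haplotype network
#'
#' Collapses the alignment to distinct haplotypes, restricts to the
#' variable sites, and builds the median-joining network: the
#' epsilon-relaxed minimum spanning network is iteratively augmented with
#' median (per-site majority consensus) vectors of linked triples whenever
#' the median shortens the minimum spanning tree of the node set, after
#' which median vectors that no longer act as branching points (degree
#' <= 2 and removable without lengthening the tree) are pruned. With
#' epsilon = 0 and tree-like data the result is the unique minimum
#' spanning tree. Equal-cost medians are tied lexicographically by their
#' sequence for reproducibility.
#'
#' @param x a HaplotypeDataset (at least two distinct haplotypes).
#' @param epsilon tolerance on link weights (default 0, the usual
#'   software default).
#' @param maxMedians safety cap on inferred median vectors.
#' @return a \linkS4class{HaploNetwork}.
#' @export
medianJoiningNetwork <- function(x, epsilon = 0, maxMedians = 50) {
  stopifnot(epsilon >= 0)
  cc <- collapseHaplotypes(x)
  if (length(cc$sequences) < 2L)
    stop("need at least two distinct haplotypes")
  full <- do.call(rbind, strsplit(cc$sequences, ""))
  varSites <- which(apply(full, 2, function(col) length(unique(col)) > 1))
  states <- full[, varSites, drop = FALSE]
  if (any(!states %in% c("A", "C", "G", "T")))
    stop("non-nucleotide characters at variable sites")
  ids <- names(cc$sequences)
  type <- rep("observed", length(ids))
  mcount <- 0
  repeat {
    d <- hammingMatrix(states)
    links <- msnLinks(d, epsilon)
    # adjacency for triple enumeration
    H <- nrow(states)
    linked <- matrix(FALSE, H, H)
    linked[links] <- TRUE; linked <- linked | t(linked)
    base <- mstEdges(d)$length
    bestGain <- 0; bestMedian <- NULL
    for (u in seq_len(H - 1)) for (v in (u + 1):H) {
      if (!linked[u, v]) next
      partners <- which(linked[u, ] | linked[v, ])
      for (w in partners[partners > v]) {
        m <- siteMedian(states[u, ], states[v, ], states[w, ])
        if (is.null(m)) next
        key <- paste(m, collapse = "")
        if (key %in% apply(states, 1, paste, collapse = "")) next
        d2 <- hammingMatrix(rbind(states, m))
        gain <- base - mstEdges(d2)$length
        if (gain > bestGain ||
            (gain == bestGain && gain > 0 &&
             !is.null(bestMedian) &&
             key < paste(bestMedian, collapse = ""))) {
          bestGain <- gain; bestMedian <- m
        }
      }
    }
    if (is.null(bestMedian) || bestGain <= 0 || mcount >= maxMedians)
      break
    mcount <- mcount + 1
    states <- rbind(states, bestMedian)
    ids <- c(ids, paste0("mv", mcount))
    type <- c(type, "median")
  }
  # prune median vectors that are not branching points
  repeat {
    d <- hammingMatrix(states)
    links <- msnLinks(d, epsilon)
    deg <- tabulate(c(links[, 1], links[, 2]), nbins = nrow(states))
    base <- mstEdges(d)$length
    drop <- NA
    for (i in which(type == "median")) {
      if (deg[i] > 2) next
      dI <- hammingMatrix(states[-i, , drop = FALSE])
      if (mstEdges(dI)$length <= base) { drop <- i; break }
    }
    if (is.na(drop)) break
    states <- states[-drop, , drop = FALSE]
    ids <- ids[-drop]; type <- type[-drop]
  }
  d <- hammingMatrix(states)
  links <- msnLinks(d, epsilon)
  rownames(states) <- ids
  edges <- data.frame(
    from = ids[links[, 1]], to = ids[links[, 2]],
    steps = d[links],
    positions = apply(links, 1, function(e)
      paste(varSites[states[e[1], ] != states[e[2], ]], collapse = ",")),
    stringsAsFactors = FALSE)
  freq <- rowSums(cc$counts)
  nodes <- data.frame(id = ids, type = type,
                      freq = c(freq, rep(0, sum(type == "median"))),
                      stringsAsFactors = FALSE)
  new("HaploNetwork", nodes = nodes, edges = edges, popFreq = cc$counts,
      haplotypes = states, variableSites = as.integer(varSites))
}

#' Edge list of a haplotype network
#'
#' @param net a HaploNetwork.
#' @return data.frame from, to, steps, positions -- suitable for writing
#'   as CSV or for building an igraph object.
#' @export
networkEdges <- function(net) net@edges

#' Per-node locality frequencies of a haplotype network
#'
#' @param net a HaploNetwork.
#' @return matrix haplotype x locality of observed counts (pie-chart
#'   ready; median vectors have zero rows omitted).
#' @export
networkPopFreq <- function(net) net@popFreq

#' Shortest path length between two nodes of the network
#'
#' Steps are summed along the network's edges (Dijkstra); used e.g. to
#' report the minimum number of mutation steps between two haplogroups.
#'
#' @param net a HaploNetwork.
#' @param from,to node ids.
#' @return numeric step count (Inf if disconnected).
#' @export
networkDistance <- function(net, from, to) {
  ids <- net@nodes$id
  n <- length(ids)
  dist <- setNames(rep(Inf, n), ids)
  dist[from] <- 0
  visited <- setNames(rep(FALSE, n), ids)
  repeat {
    u <- names(which.min(ifelse(visited, Inf, dist)))
    if (!length(u) || !is.finite(dist[u])) break
    if (u == to) return(unname(dist[u]))
    visited[u] <- TRUE
    adj <- rbind(net@edges[net@edges$from == u, c("to", "steps")],
                 setNames(net@edges[net@edges$to == u,
                                    c("from", "steps")],
                          c("to", "steps")))
    for (r in seq_len(nrow(adj))) {
      v <- adj$to[r]
      if (dist[u] + adj$steps[r] < dist[v])
        dist[v] <- dist[u] + adj$steps[r]
    }
    if (all(visited | !is.finite(dist))) break
  }
  unname(dist[to])
}
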