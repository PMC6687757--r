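# Independent oracles used across the suite. These deliberately take
# the slow, literal route (exhaustive enumeration, flood fill, direct
# path counting) so they share no code path with the implementation.

# Betweenness by direct all-pairs shortest-path counting: sigma[s, t]
# path counts from layered BFS, then score(v) += sigma(s,v) * sigma(v,t)
# / sigma(s,t) whenever d(s,v) + d(v,t) = d(s,t).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sg <- rep(0, n); sg[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (!is.finite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d; sigma[s, ] <- sg
  }
  score <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(dist[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          score[v] <- score[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  score
}

# Connected components by iterative flood fill over an explicit stack.
brute_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- cur
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Literal transcription of the published four-siRNA hit sentence:
# a suppressor needs a strong rescue from 50% of the siRNAs, or a
# weak (or better) rescue from three out of four.
literal_four_sirna_rule <- function(strengths) {
  stopifnot(length(strengths) == 4)
  strong_half <- sum(strengths == "strong") >= 0.5 * 4
  weak_three <- sum(strengths %in% c("weak", "strong")) >= 3
  strong_half || weak_three
}

# All ordered strength vectors of length n.
all_strength_vectors <- function(n) {
  lv <- c("none", "weak", "strong")
  as.matrix(do.call(expand.grid,
                    c(rep(list(lv), n), stringsAsFactors = FALSE)))
}

# Sensitivity/specificity of target calls against planted truth.
screen_recovery <- function(screen, result) {
  tc <- merge(result$target_calls,
              screen$truth[, c("target", "suppressive_zw10",
                               "suppressive_cog3")], by = "target")
  pred <- c(tc$suppress_zw10, tc$suppress_cog3)
  truth <- c(tc$suppressive_zw10, tc$suppressive_cog3)
  keep <- !is.na(pred)
  pred <- pred[keep]; truth <- truth[keep]
  c(sensitivity = sum(pred & truth) / sum(truth),
    specificity = sum(!pred & !truth) / sum(!truth))
}

# Random simple graph as an adjacency matrix + records table.
random_graph_fixture <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0L, n_nodes, n_nodes)
  ids <- sprintf("V%02d", seq_len(n_nodes))
  rec <- NULL
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) {
        adj[i, j] <- adj[j, i] <- 1L
        rec <- rbind(rec, data.frame(
          interactor_a = ids[i], interactor_b = ids[j],
          detection_method = "pull down",
          interaction_type = "physical association",
          confidence = 0.9, stringsAsFactors = FALSE))
      }
    }
  }
  list(adj = adj, ids = ids, records = rec)
}
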