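# Independent oracles used across the suite. These deliberately use naive
# enumeration/brute force, not the package's code paths.

# All global alignments of two short sequences under affine-gap scoring
# (match/mismatch/open/extend); returns a data frame of (score, identity)
# over complete alignments. Exponential - keep sequences short.
enumerate_alignments <- function(a, b, match = 1, mismatch = 0,
                                 gap_open = -10, gap_extend = -0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  out <- list()
  rec <- function(i, j, score, matches, len, last) {
    if (i > length(ca) && j > length(cb)) {
      out[[length(out) + 1]] <<- c(score = score, identity = matches / len)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      rec(i + 1, j + 1, score + s, matches + (ca[i] == cb[j]), len + 1, "M")
    }
    if (i <= length(ca)) {
      g <- if (last == "X") gap_extend else gap_open + gap_extend
      rec(i + 1, j, score + g, matches, len + 1, "X")
    }
    if (j <= length(cb)) {
      g <- if (last == "Y") gap_extend else gap_open + gap_extend
      rec(i, j + 1, score + g, matches, len + 1, "Y")
    }
  }
  rec(1, 1, 0, 0, 0, "start")
  as.data.frame(do.call(rbind, out))
}

# identities achieved by score-optimal alignments
oracle_identity_set <- function(a, b, tol = 1e-9) {
  al <- enumerate_alignments(a, b)
  unique(al$identity[al$score >= max(al$score) - tol])
}

# O(n^2) atom-pair contact scan: interacting residues of `chain` against
# all `partner_chains` of a complex, by triple loop.
oracle_contact_residues <- function(s, chain, partner_chains, cutoff) {
  a1 <- s$atoms[s$atoms$chain_id == chain, ]
  a2 <- s$atoms[s$atoms$chain_id %in% partner_chains, ]
  hits <- character()
  for (i in seq_len(nrow(a1))) {
    for (j in seq_len(nrow(a2))) {
      d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                  (a1$z[i] - a2$z[j])^2)
      if (d <= cutoff) hits <- c(hits, paste(a1$seq_num[i], a1$insertion_code[i]))
    }
  }
  unique(hits)
}

# connected components of interacting residues under the linkage rule, by
# repeated label propagation over a brute-force adjacency matrix.
oracle_site_components <- function(s, keys, link_cutoff) {
  k <- nrow(keys)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    ai <- s$atoms[s$atoms$chain_id == keys$chain_id[i] &
                    s$atoms$seq_num == keys$seq_num[i] &
                    s$atoms$insertion_code == keys$insertion_code[i], ]
    for (j in seq_len(k)) {
      aj <- s$atoms[s$atoms$chain_id == keys$chain_id[j] &
                      s$atoms$seq_num == keys$seq_num[j] &
                      s$atoms$insertion_code == keys$insertion_code[j], ]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          dmin <- min(dmin, sqrt(sum((unlist(ai[p, c("x", "y", "z")]) -
                                        unlist(aj[q, c("x", "y", "z")]))^2)))
        }
      }
      adj[i, j] <- dmin <= link_cutoff
    }
  }
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (adj[i, j] && comp[j] > comp[i]) {
          comp[j] <- comp[i]
          changed <- TRUE
        } else if (adj[i, j] && comp[i] > comp[j]) {
          comp[i] <- comp[j]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Exhaustive AD-Tree oracle: nested-list tree, naive search of every
# (prediction node, feature, threshold) with direct weight sums.
oracle_adtree <- function(x, y_log, iterations) {
  n <- nrow(x)
  y <- ifelse(y_log, 1, -1)
  w <- rep(1, n)
  eps <- 1 / n
  root_value <- 0.5 * log(sum(w[y > 0]) / sum(w[y < 0]))
  w <- w * exp(-y * root_value)
  preds <- list(list(cond = rep(TRUE, n))) # prediction nodes, root first
  rules <- list()
  for (it in seq_len(iterations)) {
    total_w <- sum(w)
    best <- NULL
    for (p in seq_along(preds)) {
      inp <- preds[[p]]$cond
      if (!any(inp)) next
      for (f in seq_len(ncol(x))) {
        v <- sort(unique(x[inp, f]))
        if (length(v) < 2) next
        for (t in (head(v, -1) + tail(v, -1)) / 2) {
          yes <- inp & x[, f] <= t
          no <- inp & x[, f] > t
          z <- 2 * (sqrt(sum(w[yes & y > 0]) * sum(w[yes & y < 0])) +
                      sqrt(sum(w[no & y > 0]) * sum(w[no & y < 0]))) +
            (total_w - sum(w[inp]))
          better <- is.null(best) || z < best$z - 1e-12 ||
            (abs(z - best$z) <= 1e-12 &&
               (f < best$f || (f == best$f && (t < best$t - 1e-12 ||
                  (abs(t - best$t) <= 1e-12 && p < best$p)))))
          if (better) best <- list(z = z, p = p, f = f, t = t)
        }
      }
    }
    if (is.null(best)) break
    inp <- preds[[best$p]]$cond
    yes <- inp & x[, best$f] <= best$t
    no <- inp & x[, best$f] > best$t
    a_yes <- 0.5 * log((sum(w[yes & y > 0]) + eps) / (sum(w[yes & y < 0]) + eps))
    a_no <- 0.5 * log((sum(w[no & y > 0]) + eps) / (sum(w[no & y < 0]) + eps))
    w[yes] <- w[yes] * exp(-y[yes] * a_yes)
    w[no] <- w[no] * exp(-y[no] * a_no)
    preds <- c(preds, list(list(cond = yes)), list(list(cond = no)))
    rules[[it]] <- list(f = best$f, t = best$t, a_yes = a_yes, a_no = a_no,
                        parent = best$p,
                        yes_id = length(preds) - 1L, no_id = length(preds))
  }
  list(root_value = root_value, rules = rules, n = n)
}

oracle_adtree_score <- function(model, x) {
  n <- nrow(x)
  margin <- rep(model$root_value, n)
  reach <- list(rep(TRUE, n))
  for (r in model$rules) {
    inp <- reach[[r$parent]]
    yes <- inp & x[, r$f] <= r$t
    no <- inp & x[, r$f] > r$t
    margin[yes] <- margin[yes] + r$a_yes
    margin[no] <- margin[no] + r$a_no
    reach[[r$yes_id]] <- yes
    reach[[r$no_id]] <- no
  }
  margin
}
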