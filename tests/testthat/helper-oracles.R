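# Independent oracles used across the suite. These deliberately share no
# code with the package: the scanner oracle enumerates every coordinating
# quadruple with nested loops, the hypergeometric oracle counts draws by
# exhaustive enumeration, and the linkage oracle recomputes average-linkage
# heights from the raw pairwise distances.

# Brute-force domain scanner: enumerate all (c1, c2, h1, h2) quadruples,
# then greedily accept, leftmost c1 first, ranking candidates by
# |spacer - 12| (ties -> smaller spacer), then h_gap, then c_gap; remove
# quadruples starting at or before the accepted second histidine.
oracle_scan <- function(seq, c_gap = c(1, 4), spacer = c(6, 25), h_gap = c(1, 8)) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  quads <- list()
  for (c1 in seq_len(n)) {
    if (res[c1] != "C") next
    for (c2 in seq_len(n)) {
      if (res[c2] != "C") next
      cg <- c2 - c1 - 1
      if (cg < c_gap[1] || cg > c_gap[2]) next
      for (h1 in seq_len(n)) {
        if (res[h1] != "H" || h1 < 6) next
        sp <- h1 - c2 - 1
        if (sp < spacer[1] || sp > spacer[2]) next
        for (h2 in seq_len(n)) {
          if (res[h2] != "H") next
          hg <- h2 - h1 - 1
          if (hg < h_gap[1] || hg > h_gap[2]) next
          quads[[length(quads) + 1]] <- c(c1 = c1, c2 = c2, h1 = h1, h2 = h2,
                                          c_gap = cg, spacer = sp, h_gap = hg)
        }
      }
    }
  }
  accepted <- list()
  if (length(quads) == 0) {
    return(data.frame(c1 = integer(), c2 = integer(), h1 = integer(),
                      h2 = integer()))
  }
  q <- do.call(rbind, quads)
  repeat {
    if (nrow(q) == 0) break
    left <- q[q[, "c1"] == min(q[, "c1"]), , drop = FALSE]
    o <- order(abs(left[, "spacer"] - 12), left[, "spacer"],
               left[, "h_gap"], left[, "c_gap"])
    best <- left[o[1], ]
    accepted[[length(accepted) + 1]] <- best
    q <- q[q[, "c1"] > best[["h2"]], , drop = FALSE]
  }
  as.data.frame(do.call(rbind, accepted))
}

# Exhaustive hypergeometric tails: enumerate every size-n study subset of a
# population of N genes of which the first K carry the term.
oracle_hyper <- function(k, K, n, N) {
  draws <- combn(N, n)
  overlap <- colSums(draws <= K)
  c(over = mean(overlap >= k), under = mean(overlap <= k))
}

# Average-linkage heights for three items from a distance matrix, by hand.
oracle_avg_linkage3 <- function(d12, d13, d23) {
  first <- min(d12, d13, d23)
  if (d12 <= d13 && d12 <= d23) second <- mean(c(d13, d23))
  else if (d13 <= d12 && d13 <= d23) second <- mean(c(d12, d23))
  else second <- mean(c(d12, d13))
  c(first = first, second = second)
}

random_protein <- function(n, alphabet = c(LETTERS[LETTERS %in% c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P","S","T","W","Y","V")])) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

scan_to_df <- function(domains) {
  as.data.frame(domains[, c("c1", "c2", "h1", "h2")])
}
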