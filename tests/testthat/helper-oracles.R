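# Independent oracles, deliberately written as plain loops and kept free of
# the package's own code paths (and of Biostrings).

# Invertebrate mitochondrial code (NCBI transl_table 5), typed from the
# standard 64-codon layout: first base T/C/A/G, second T/C/A/G, third T/C/A/G.
oracle_code5 <- local({
  aas <- strsplit("FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG", "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- character(64)
  k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_sense_codons <- names(oracle_code5)[oracle_code5 != "*"]

# synonymous site count by exhaustive enumeration of the 9 single-base
# neighbours, stop mutations excluded from the position denominator
oracle_sites <- function(codon, exclude_stops = TRUE) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (bb in bases) {
      if (bb == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- bb
      if (exclude_stops && oracle_code5[[mut]] == "*") next
      valid <- valid + 1
      if (oracle_code5[[mut]] == oracle_code5[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# all orderings of a vector, recursively
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# pathway-averaged syn/nonsyn differences between two sense codons
oracle_pathway <- function(c1, c2, exclude_stops = TRUE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  res <- list()
  for (ord in oracle_perms(pos)) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code5[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (oracle_code5[[cur]] == oracle_code5[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1L]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  if (exclude_stops) {
    open <- Filter(function(r) !r$blocked, res)
    if (length(open) > 0L) res <- open
  }
  c(sd = mean(sapply(res, `[[`, "sd")), nd = mean(sapply(res, `[[`, "nd")))
}

# junction gaps by brute-force position walking on the circle: for each
# adjacent pair, walk forward from the upstream end to the downstream start
# counting uncovered positions (spacer), or count positions covered by both
# spans (overlap)
oracle_junctions <- function(tab) {
  L <- attr(tab, "genome_length")
  n <- nrow(tab)
  covered_by <- function(i) {
    if (tab$end[i] >= tab$start[i]) seq.int(tab$start[i], tab$end[i])
    else c(seq.int(tab$start[i], L), seq.int(1L, tab$end[i]))
  }
  pairs <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  if (!attr(tab, "circular")) pairs <- pairs[-n, , drop = FALSE]
  gaps <- integer(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; d <- pairs[r, 2]
    if (tab$start[d] %in% covered_by(u)) {
      ## downstream starts inside the upstream span: overlap, counted as the
      ## positions the two (non-nested) spans share
      gaps[r] <- -length(intersect(covered_by(u), covered_by(d)))
    } else {
      ## walk forward from the base after the upstream end to the downstream
      ## start, counting intervening positions
      end_u <- if (tab$end[u] >= tab$start[u]) tab$end[u] else tab$end[u] + L
      p <- (end_u %% L) + 1L
      walk <- 0L
      while (p != tab$start[d]) {
        walk <- walk + 1L
        p <- (p %% L) + 1L
        if (walk > L) stop("oracle walked the whole circle")
      }
      gaps[r] <- walk
    }
  }
  data.frame(upstream = tab$gene[pairs[, 1]], downstream = tab$gene[pairs[, 2]],
             gap = gaps, stringsAsFactors = FALSE)
}

# random non-degenerate circular gene tables for property tests
random_table <- function(n_feat = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(50:300, n_feat, replace = TRUE)
  gaps <- integer(n_feat)
  for (i in seq_len(n_feat - 1L)) {
    max_ov <- min(lens[i], lens[i + 1L]) - 2L
    gaps[i] <- sample(seq.int(-min(20L, max_ov), 40L), 1L)
  }
  gaps[n_feat] <- sample(0:40, 1L)
  starts <- cumsum(c(1L, lens[-n_feat] + gaps[-n_feat]))
  L <- starts[n_feat] + lens[n_feat] - 1L + gaps[n_feat]
  feats <- do.call(rbind, lapply(seq_len(n_feat), function(i)
    feature(paste0("g", i), "PCG", "H", starts[i], starts[i] + lens[i] - 1L,
            declared_length = lens[i])))
  gene_table(feats, genome_length = L, circular = TRUE)
}

# rotate every coordinate of a circular table by `off` bp
rotate_table <- function(tab, off) {
  L <- attr(tab, "genome_length")
  shift <- function(x) ((x - 1L + off) %% L) + 1L
  df <- as.data.frame(tab)
  df$start <- shift(df$start)
  df$end <- shift(df$end)
  gene_table(df, genome_length = L, circular = attr(tab, "circular"))
}
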