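## Pairwise synonymous (ks) and nonsynonymous (ka) substitution rates in the
## Nei-Gojobori (1986) counting framework: fractional synonymous/
## nonsynonymous site counts per codon, pathway-averaged difference counts
## per codon pair, proportions corrected with the Jukes-Cantor formula
## d = -(3/4) ln(1 - (4/3) p). This is the method classical population-
## genetics software applies for ka/ks on coding alignments.

NT <- c("A", "C", "G", "T")

#' Synonymous/nonsynonymous site counts of one codon
#'
#' Each of the three positions contributes one site, split into a synonymous
#' fraction (the fraction of its single-base mutations that preserve the
#' amino acid) and a nonsynonymous remainder, so `s + n = 3` exactly. With
#' `exclude_stop_mutations = TRUE` (the default, and the common convention),
#' mutations creating a stop codon are removed from a position's denominator.
#'
#' @param codon 3-mer over `A`, `C`, `G`, `T`; must not be a stop codon.
#' @param code_id genetic code (default 5).
#' @param exclude_stop_mutations drop mutations to stop codons from the
#'   denominator?
#' @return named numeric vector `c(s = ..., n = ...)`.
#' @export
ng86_sites <- function(codon, code_id = 5, exclude_stop_mutations = TRUE) {
  code <- genetic_code(code_id)
  codon <- toupper(codon)
  if (is.na(code[codon])) stop("not an unambiguous codon: ", codon)
  if (code[codon] == "*") stop("stop codon ", codon, " has no site counts")
  aa0 <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(NT, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (exclude_stop_mutations && code[[mut]] == "*") next
      valid <- valid + 1L
      if (code[[mut]] == aa0) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# site counts for every sense codon, as a matrix (rows = codons)
ng86_site_table <- function(code_id = 5, exclude_stop_mutations = TRUE) {
  code <- genetic_code(code_id)
  sense <- names(code)[code != "*"]
  t(vapply(sense, ng86_sites, numeric(2), code_id = code_id,
           exclude_stop_mutations = exclude_stop_mutations))
}

# all orderings of 1..n (n <= 3 here)
perm_orders <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perm_orders(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, (seq_len(n)[-i])[rest])
    }
  }
  out
}

# pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. Pathways through stop codons are discarded; if every ordering is
# blocked, the average falls back to all orderings (documented choice).
ng86_codon_diffs <- function(c1, c2, code, exclude_stop_paths = TRUE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  classify <- function(order) {
    cur <- c1; sd <- 0L; nd <- 0L; blocked <- FALSE
    for (p in pos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  paths <- lapply(perm_orders(k), classify)
  if (exclude_stop_paths) {
    open <- Filter(function(p) !p$blocked, paths)
    if (length(open) > 0L) paths <- open
  }
  c(sd = mean(vapply(paths, `[[`, integer(1), "sd")),
    nd = mean(vapply(paths, `[[`, integer(1), "nd")))
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' @param p proportion of differing sites per site.
#' @return `-(3/4) log(1 - (4/3) p)`; `NA` when `p >= 3/4` (saturation).
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise ka/ks for two in-frame coding sequences
#'
#' Nei-Gojobori (1986) counting with pathway averaging over the up-to-3!
#' substitution orderings per codon pair (orderings passing through a stop
#' codon are discarded; if all are blocked the average is taken over all
#' orderings) and Jukes-Cantor multiple-hit correction. Codons containing
#' gaps or ambiguous bases in either sequence, and codon pairs where either
#' codon is a stop, are skipped and counted in `excluded_codons`.
#'
#' @param a,b nucleotide strings of equal length, a multiple of 3.
#' @param code_id genetic code (default 5).
#' @param exclude_stop_mutations see [ng86_sites()].
#' @return object of class `rate_pair`: list with `S`, `N` (site counts
#'   averaged over the two sequences), `Sd`, `Nd`, `ps`, `pn`, `ks`, `ka`,
#'   `omega` (`ka/ks`; `NA` when `ks` is 0 or undefined), `n_codons`
#'   (compared), `excluded_codons`.
#' @export
pairwise_kaks <- function(a, b, code_id = 5, exclude_stop_mutations = TRUE) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  code <- genetic_code(code_id)
  site_tab <- ng86_site_table(code_id, exclude_stop_mutations)
  n3 <- nchar(a) %/% 3L
  ca <- substring(a, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
  cb <- substring(b, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
  ok <- ca %in% rownames(site_tab) & cb %in% rownames(site_tab)
  ca <- ca[ok]; cb <- cb[ok]
  S <- (sum(site_tab[ca, "s"]) + sum(site_tab[cb, "s"])) / 2
  N <- (sum(site_tab[ca, "n"]) + sum(site_tab[cb, "n"])) / 2
  memo <- new.env(parent = emptyenv())
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    key <- paste0(ca[i], cb[i])
    d <- memo[[key]]
    if (is.null(d)) {
      d <- ng86_codon_diffs(ca[i], cb[i], code, exclude_stop_mutations)
      memo[[key]] <- d
    }
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  omega <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ks = ks, ka = ka, omega = omega,
                 n_codons = length(ca), excluded_codons = n3 - length(ca)),
            class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("S=%.2f N=%.2f Sd=%.2f Nd=%.2f | ks=%.4f ka=%.4f ka/ks=%s (%d codons, %d excluded)\n",
              x$S, x$N, x$Sd, x$Nd, x$ks, x$ka,
              ifelse(is.na(x$omega), "NA", sprintf("%.4f", x$omega)),
              x$n_codons, x$excluded_codons))
  invisible(x)
}

#' Per-taxon mean substitution rates over an alignment
#'
#' For every taxon, the mean `ks` and mean `ka` over all pairwise
#' comparisons containing it (the default), or over its single comparison
#' with a designated reference sequence. Pairs with an undefined (saturated)
#' distance are excluded from the mean and counted.
#'
#' @param alignment named character vector of equal-length in-frame
#'   sequences (>= 2).
#' @param code_id genetic code (default 5).
#' @param reference optional taxon name: compare every taxon against this
#'   sequence only.
#' @param exclude_stop_mutations see [ng86_sites()].
#' @return `data.frame`: `taxon`, `mean_ks`, `mean_ka`, `ratio`
#'   (`mean_ka / mean_ks`), `n_pairs`, `excluded_pairs`.
#' @export
taxon_mean_rates <- function(alignment, code_id = 5, reference = NULL,
                             exclude_stop_mutations = TRUE) {
  if (length(alignment) < 2L) stop("alignment must contain at least 2 sequences")
  if (is.null(names(alignment)) || anyNA(names(alignment)))
    stop("alignment sequences must be named")
  taxa <- names(alignment)
  if (!is.null(reference) && !reference %in% taxa)
    stop("reference taxon not in alignment: ", reference)
  pairs <- utils::combn(taxa, 2L, simplify = FALSE)
  if (!is.null(reference))
    pairs <- Filter(function(p) reference %in% p, pairs)
  rp <- lapply(pairs, function(p)
    pairwise_kaks(alignment[[p[1]]], alignment[[p[2]]], code_id,
                  exclude_stop_mutations))
  rows <- lapply(taxa, function(tx) {
    mine <- if (is.null(reference)) {
      vapply(pairs, function(p) tx %in% p, logical(1))
    } else if (tx == reference) {
      rep(TRUE, length(pairs))
    } else {
      vapply(pairs, function(p) tx %in% p, logical(1))
    }
    ks <- vapply(rp[mine], `[[`, numeric(1), "ks")
    ka <- vapply(rp[mine], `[[`, numeric(1), "ka")
    usable <- !is.na(ks) & !is.na(ka)
    mean_ks <- if (any(usable)) mean(ks[usable]) else NA_real_
    mean_ka <- if (any(usable)) mean(ka[usable]) else NA_real_
    data.frame(taxon = tx, mean_ks = mean_ks, mean_ka = mean_ka,
               ratio = if (!is.na(mean_ks) && mean_ks > 0) mean_ka / mean_ks
                       else NA_real_,
               n_pairs = sum(usable), excluded_pairs = sum(!usable),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pairs") <- rp
  attr(out, "pair_names") <- pairs
  out
}
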