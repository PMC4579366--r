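# Independent oracles for relatedness checks. Both are deliberately naive
# pure-R implementations kept apart from the package's tabular algorithms.

# Memoised textbook recursion for the kinship coefficient:
#   f(x, y)      = (f(sire_x, y) + f(dam_x, y)) / 2   (x not an ancestor of y)
#   f(x, x)      = (1 + f(sire_x, dam_x)) / 2
#   f(., unknown) = 0
# Expanding the topologically later member of each pair guarantees the
# "not an ancestor" condition. Returns a closure over the pedigree.
naive_kinship_fun <- function(p) {
  r <- p$records
  n <- nrow(r)
  rank <- integer(n)
  rank[p$topo] <- seq_len(n)
  si <- p$sire_idx
  di <- p$dam_idx
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    if (i == j) {
      v <- 0.5 * (1 + f(si[i], di[i]))
    } else {
      if (rank[i] > rank[j]) { a <- i; b <- j } else { a <- j; b <- i }
      v <- 0.5 * (f(si[a], b) + f(di[a], b))
    }
    memo[[key]] <- v
    v
  }
  function(aid, bid) f(match(aid, r$id), match(bid, r$id))
}

# Inbreeding of every animal by the naive recursion: F_x = f(sire_x, dam_x).
naive_inbreeding <- function(p) {
  f <- naive_kinship_fun(p)
  r <- p$records
  out <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (p$sire_idx[i] == 0L || p$dam_idx[i] == 0L) next
    out[i] <- f(r$sire[i], r$dam[i])
  }
  setNames(out, r$id)
}

# Gene-dropping Monte Carlo estimate of F: founders (and each unknown
# parental side) receive unique alleles; alleles are transmitted down the
# pedigree by fair coin; F-hat is the fraction of drops in which an animal's
# two alleles are identical by descent. Vectorised across drops.
gene_drop_inbreeding <- function(p, ndrops = 2e5, seed = 1) {
  set.seed(seed)
  n <- nrow(p$records)
  si <- p$sire_idx
  di <- p$dam_idx
  a1 <- vector("list", n)
  a2 <- vector("list", n)
  next_allele <- 0L
  Fhat <- numeric(n)
  transmit <- function(g1, g2) {
    swap <- runif(length(g1)) < 0.5
    out <- g1
    out[swap] <- g2[swap]
    out
  }
  for (i in p$topo) {
    if (si[i] == 0L) {
      next_allele <- next_allele + 1L
      a1[[i]] <- rep.int(next_allele, ndrops)
    } else a1[[i]] <- transmit(a1[[si[i]]], a2[[si[i]]])
    if (di[i] == 0L) {
      next_allele <- next_allele + 1L
      a2[[i]] <- rep.int(next_allele, ndrops)
    } else a2[[i]] <- transmit(a1[[di[i]]], a2[[di[i]]])
    Fhat[i] <- mean(a1[[i]] == a2[[i]])
  }
  setNames(Fhat, p$records$id)
}
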