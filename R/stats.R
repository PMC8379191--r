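#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness z-score (D'Agostino 1970)
#' and kurtosis z-score (Anscombe-Glynn 1983) into the omnibus
#' `K2 = Zs^2 + Zk^2`, referred to a chi-square distribution with two
#' degrees of freedom. Requires n >= 8, below which the kurtosis
#' transform is undefined.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K2), `p.value`, `zSkew`, `zKurt`,
#'   `n`.
#' @export
dagostinoTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    stop("the D'Agostino normality test requires n >= 8 (got ", n, ")")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample has zero variance")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  ## skewness transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  ## kurtosis transform
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- zs^2 + zk^2
  list(statistic = K2, p.value = pchisq(K2, 2, lower.tail = FALSE),
       zSkew = zs, zKurt = zk, n = n)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact two-tailed p by the exact null distribution of U when
#' `length(a) * length(b) <= 400` and the pooled data are tie free;
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b numeric samples; both must be non-empty.
#' @param method `"auto"` (default branch rule), or force `"exact"` /
#'   `"normal"` (exact still requires tie-free data).
#' @return list with `U` (statistic for sample `a`), `p.value`,
#'   `method` ("exact" or "normal").
#' @export
mannWhitney <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  useExact <- if (method == "auto") !ties && na * nb <= 400
  else method == "exact"
  if (useExact && ties) stop("exact method requires tie-free data")
  if (useExact) {
    pl <- pwilcox(U, na, nb)
    pu <- pwilcox(U - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(pl, pu))
    method <- "exact"
  } else {
    N <- na + nb
    tie <- table(pooled)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p.value = p, method = method)
}

#' Paired two-tailed t-test
#'
#' t on the paired differences with n - 1 degrees of freedom. All-zero
#' differences return p = 1 by convention (no evidence of a shift);
#' identical non-zero differences make t undefined and raise an error.
#'
#' @param a,b equal-length paired samples, n >= 2.
#' @return list with `t`, `df`, `p.value`, `meanDiff`.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2L) stop("paired t needs n >= 2")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p.value = 1, meanDiff = 0))
    stop("zero-variance non-zero differences; t is undefined")
  }
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1,
       p.value = 2 * pt(-abs(t), n - 1), meanDiff = mean(d))
}

#' Compare two groups for one measure
#'
#' The reported analysis flow: per-group D'Agostino normality (when a
#' group reaches n >= 8; recorded, not used to switch tests), then a
#' two-tailed Mann-Whitney for unpaired contrasts or a paired
#' two-tailed t-test when `paired = TRUE` (values are then paired by
#' `animalId`, e.g. central vs peripheral per animal).
#'
#' @param table data.frame with columns `animalId`, `ageGroup` (or the
#'   column named by `groupCol`), `measure`, `value`.
#' @param measure measure name to select.
#' @param paired pair values by `animalId` across the two groups.
#' @param groupCol name of the grouping column.
#' @return list with `test`, `statistic`, `p.value`, `groups` (summary
#'   data.frame: group, n, mean, sd), `normality` (per-group list or
#'   NULL).
#' @export
compareGroups <- function(table, measure, paired = FALSE,
                          groupCol = "ageGroup") {
  tab <- table[table$measure == measure, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for measure '", measure, "'")
  grp <- factor(tab[[groupCol]])
  if (nlevels(grp) != 2L)
    stop("exactly two groups are required (found ", nlevels(grp), ")")
  g1 <- levels(grp)[1L]; g2 <- levels(grp)[2L]
  v1 <- tab$value[grp == g1]; v2 <- tab$value[grp == g2]
  normality <- lapply(setNames(list(v1, v2), c(g1, g2)), function(v)
    if (length(v) >= 8L && sd(v) > 0) dagostinoTest(v) else NULL)
  if (paired) {
    id1 <- tab$animalId[grp == g1]; id2 <- tab$animalId[grp == g2]
    if (anyDuplicated(id1) || anyDuplicated(id2) ||
        !setequal(id1, id2) || length(id1) != length(id2))
      stop("paired comparison requires matching animal ids across groups")
    o <- match(id1, id2)
    tst <- pairedT(v1, v2[o])
    res <- list(test = "paired t", statistic = tst$t,
                p.value = tst$p.value)
  } else {
    tst <- mannWhitney(v1, v2)
    res <- list(test = paste0("Mann-Whitney (", tst$method, ")"),
                statistic = tst$U, p.value = tst$p.value)
  }
  res$groups <- data.frame(group = c(g1, g2),
                           n = c(length(v1), length(v2)),
                           mean = c(mean(v1), mean(v2)),
                           sd = c(sd(v1), sd(v2)))
  res$normality <- normality
  res
}
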