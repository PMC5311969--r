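stat_result <- function(test, statistic, p_value, n, method,
                        p_adjusted = NA_real_, z = NA_real_,
                        group1 = NA_character_, group2 = NA_character_) {
  tibble(test = test, group1 = group1, group2 = group2,
         statistic = statistic, z = z, p_value = p_value,
         p_adjusted = p_adjusted, n = n, method = method)
}

#' Spearman rank correlation
#'
#' Ranks with average-rank ties; rho is the Pearson correlation of the two
#' rank vectors. The p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` by default, or an exact permutation
#' enumeration over all orderings for n <= 8 (`method = "auto"`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param p_method `"auto"`, `"t"` or `"exact"`.
#' @return a one-row stats tibble (`test`, `statistic`, `p_value`, `n`, ...).
#' @export
spearman_rho <- function(x, y, p_method = c("auto", "t", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop_fmt("spearman_rho requires n >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_fmt("zero variance in a rank vector")
  }
  rho <- cor(rx, ry)
  if (p_method == "auto") p_method <- if (n <= 8) "exact" else "t"
  if (p_method == "exact") {
    if (n > 8) stop_fmt("exact permutation p limited to n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p <- min(1, p)
    method <- "approximate"
  }
  stat_result("spearman", rho, p, n, method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Bonferroni adjustment
#'
#' Each p-value multiplied by the family size, capped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Mann-Whitney U test
#'
#' Reports the U statistic of group 1, the tie-corrected normal
#' approximation Z (no continuity correction), and an exact two-sided p
#' obtained by enumerating all C(n1+n2, n1) group labelings when the total
#' sample size is within `exact_limit` (the exact p is the headline; the
#' approximate p is reported alongside since small-sample software output
#' often prints the Z regime).
#'
#' @param group1,group2 numeric vectors.
#' @param exact_limit largest `n1+n2` for which labelings are enumerated.
#' @return a one-row stats tibble; `statistic` is U1, `method` `"exact"` or
#'   `"approximate"`, and attribute `p_approx` carries the normal p.
#' @export
mann_whitney_u <- function(group1, group2, exact_limit = 12L) {
  n1 <- length(group1)
  n2 <- length(group2)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(group1, group2)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0
  p_approx <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1

  if (nn <= exact_limit) {
    combs <- combn(nn, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u1 - mu) - 1e-12)
    res <- stat_result("mann_whitney_u", u1, p, nn, "exact", z = z)
  } else {
    res <- stat_result("mann_whitney_u", u1, p_approx, nn, "approximate", z = z)
  }
  attr(res, "p_approx") <- p_approx
  res
}

#' Fisher's exact test for an r x c table
#'
#' Exact two-sided p by recursive enumeration of all tables with the
#' observed margins: the p-value is the total multivariate hypergeometric
#' probability of tables no more probable than the observed one
#' (probability-at-most-observed rule, with a small relative tolerance for
#' floating-point ties). Degenerate margins (a zero row or column) give
#' p = 1.
#'
#' @param table matrix of non-negative integer counts; total at most
#'   `max_total` (enumeration bound).
#' @param max_total largest permitted table total.
#' @return a one-row stats tibble (`statistic` is the observed table
#'   probability).
#' @export
fisher_exact <- function(table, max_total = 500L) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop_fmt("fisher_exact requires non-negative integer counts")
  }
  n <- sum(m)
  if (n > max_total) {
    stop_fmt("table total %d exceeds enumeration bound %d; consider a Monte Carlo approximation", n, max_total)
  }
  rs <- rowSums(m)
  cs <- colSums(m)
  m <- m[rs > 0, cs > 0, drop = FALSE]
  rs <- rowSums(m)
  cs <- colSums(m)
  if (nrow(m) < 2 || ncol(m) < 2 || n == 0) {
    return(stat_result("fisher_exact", 1, 1, n, "exact"))
  }
  # log-probability of a table given fixed margins
  log_denom <- lgamma(n + 1) - sum(lgamma(rs + 1)) - sum(lgamma(cs + 1))
  logp_table <- function(x) -(log_denom + sum(lgamma(x + 1)))
  logp_obs <- logp_table(m)
  tol <- logp_obs + 1e-7
  nr <- nrow(m)
  nc <- ncol(m)
  p_sum <- 0
  # fill row by row, cell by cell; the last column of a row and the whole
  # last row are forced by the margins, which prunes the enumeration
  recurse <- function(row, col, col_left, row_left, logp_part) {
    if (row == nr) {
      lp <- logp_part - sum(lgamma(col_left + 1))
      if (lp <= tol) p_sum <<- p_sum + exp(lp)
      return(invisible())
    }
    if (col == nc) {
      x <- row_left
      if (x > col_left[nc]) return(invisible())
      col_left2 <- col_left
      col_left2[nc] <- col_left2[nc] - x
      recurse(row + 1L, 1L, col_left2, rs[row + 1L], logp_part - lgamma(x + 1))
      return(invisible())
    }
    rest_cap <- sum(col_left[(col + 1):nc])
    lo <- max(0L, row_left - rest_cap)
    hi <- min(row_left, col_left[col])
    if (lo > hi) return(invisible())
    for (x in lo:hi) {
      col_left2 <- col_left
      col_left2[col] <- col_left2[col] - x
      recurse(row, col + 1L, col_left2, row_left - x,
              logp_part - lgamma(x + 1))
    }
  }
  recurse(1L, 1L, cs, rs[1], -log_denom)
  stat_result("fisher_exact", exp(logp_obs), min(1, p_sum), n, "exact")
}

#' Pairwise between-hive concordance of plant use
#'
#' Spearman rank correlation of taxon abundance vectors for every hive pair,
#' per month, over the union taxon list across all hives and months (absent
#' taxa enter as zero), Bonferroni-adjusted over all pairs x months.
#'
#' @param compositions list of `sample_composition` tibbles (one per hive x
#'   month).
#' @param p_method passed to [spearman_rho()] (`"t"` by default here, the
#'   standard output regime at these n).
#' @return a stats tibble with one row per hive pair and month.
#' @export
hive_concordance <- function(compositions, p_method = "t") {
  all <- bind_rows(compositions)
  key_all <- sort(unique(paste(all$rank, all$label, sep = "\r")))
  n_taxa <- length(key_all)
  hives <- sort(unique(all$hive))
  months <- unique(all$month)
  if (length(hives) < 2) stop_fmt("hive_concordance requires >= 2 hives")
  vec <- function(h, m) {
    sub <- all[all$hive == h & all$month == m, ]
    v <- setNames(rep(0, n_taxa), key_all)
    v[paste(sub$rank, sub$label, sep = "\r")] <- sub$proportion
    v
  }
  rows <- list()
  for (m in months) {
    for (i in seq_len(length(hives) - 1)) {
      for (j in seq(i + 1, length(hives))) {
        r <- spearman_rho(vec(hives[i], m), vec(hives[j], m),
                          p_method = p_method)
        r$group1 <- paste(hives[i], m)
        r$group2 <- paste(hives[j], m)
        r$test <- "hive_concordance"
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  out <- bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_value)
  out
}

#' Association between checklist status and major/minor class
#'
#' Builds the status (native / both / horticulture) by class (major / minor)
#' contingency table over the classified honey taxa and runs the r x c
#' Fisher's exact test. Labels are matched against the checklist like
#' [regional_filter()]: exact label first, then genus; family-rank groups
#' take the status of the first constituent genus found.
#'
#' @param checklist tibble from [read_checklist()].
#' @param classified a [classify_major_minor()] composition.
#' @return list with `table` (the contingency matrix) and `result` (the
#'   [fisher_exact()] row).
#' @export
status_association <- function(checklist, classified) {
  cl_norm <- normalize_label(checklist$taxon)
  cl_genus <- genus_token(cl_norm)
  status_of <- function(i) {
    lab <- normalize_label(classified$label[i])
    cand <- if (classified$rank[i] == "family") {
      normalize_label(classified$genus_group[[i]])
    } else {
      c(lab, genus_token(lab))
    }
    hit <- which(cl_norm %in% cand | cl_genus %in% cand)
    if (length(hit) == 0) NA_character_ else checklist$status[hit[1]]
  }
  status <- vapply(seq_len(nrow(classified)), status_of, "")
  if (anyNA(status)) {
    stop_fmt("taxa without checklist status: %s",
             paste(classified$label[is.na(status)], collapse = ", "))
  }
  tab <- table(factor(status, levels = c("native", "both", "horticulture")),
               factor(classified$class, levels = c("major", "minor")))
  res <- fisher_exact(unclass(tab))
  res$test <- "status_association"
  list(table = unclass(tab), result = res)
}
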