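# Distance-based multivariate ANOVA (PERMANOVA) on Bray-Curtis matrices.
#
# The total sum of squared interpoint dissimilarities is partitioned through
# the Gower-centered inner-product matrix G = C (-1/2 D^2) C with
# C = I - 11'/n: for a design hat matrix H, SS(model) = tr(HGH) = tr(HG).
# Terms enter sequentially (Type I); pseudo-F per term is
# (SS_term/df_term) / (SS_res/df_res). Significance is assessed by
# permutation of residuals under a reduced model (Freedman-Lane): the tested
# term is dropped, residuals of the reduced fit are permuted, and the full
# model is refit to each permuted outcome. When the number of distinct row
# permutations is at most the requested count, all of them are enumerated
# and the p-value is exact.

#' Bray-Curtis dissimilarity matrix of diet profiles
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i). Any consistent scale (percent
#' or fractions) gives the same matrix; similarity = 100 * (1 - d) is
#' available for report parity via the `similarity` attribute.
#'
#' @param profiles Numeric matrix, rows = profiles on a common category set.
#' @return A symmetric matrix of dissimilarities in \[0, 1\] with zero
#'   diagonal, class `dissimilarity_matrix`; row/column names are preserved.
#' @export
bray_curtis <- function(profiles) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L) stop("need at least two profiles")
  if (any(m < 0)) stop("profiles must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero profile row(s) ", paste(which(zero), collapse = ", "),
         ": Bray-Curtis undefined")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  attr(d, "similarity") <- 100 * (1 - d)
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

# Gower-centered inner-product matrix from a dissimilarity matrix
.gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a); cm <- colMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, cm) + gm
}

# hat matrix (via QR) and rank of a design matrix
.hat <- function(X) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = qrX$rank)
}

.design_for_terms <- function(factors, terms) {
  if (!length(terms)) return(matrix(1, nrow(factors), 1L))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data = factors)
}

# all permutations of 1..n (used for exhaustive enumeration, small n only)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

#' Permutational multivariate analysis of variance
#'
#' @param dmat A square dissimilarity matrix (e.g. from [bray_curtis()]) or
#'   a `dist` object.
#' @param factors A data.frame of factors, one row per row of `dmat`.
#' @param terms Character vector of model terms in the order they enter the
#'   sequential decomposition, e.g.
#'   `c("species", "habitat", "season", "species:habitat")`.
#' @param n_perm Requested number of random permutations (default 999).
#'   If `factorial(n)` is at most `n_perm`, all distinct permutations are
#'   enumerated instead and the p-value is exact.
#' @param seed Optional integer seed for the permutation stream.
#' @return A data.frame with class `permanova_table`: one row per term plus
#'   `Residual` and `Total`, columns `df`, `SS`, `MS`, `pseudo_F`, `p_perm`,
#'   `perms`. Attribute `exhaustive` flags exact enumeration; attribute
#'   `degenerate` flags an all-identical input (tests undefined, not p = 0).
#' @export
permanova <- function(dmat, factors, terms, n_perm = 999L, seed = NULL) {
  d <- as.matrix(dmat)
  n <- nrow(d)
  if (ncol(d) != n) stop("dmat must be square")
  factors <- as.data.frame(factors)
  if (nrow(factors) != n) stop("factors must have one row per dmat row")
  for (v in all.vars(stats::as.formula(paste("~", paste(terms, collapse = "+"))))) {
    if (!v %in% names(factors)) stop("factor ", sQuote(v), " not found")
    if (anyNA(factors[[v]])) stop("factor ", sQuote(v), " has missing levels")
    factors[[v]] <- factor(factors[[v]])
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")

  G <- .gower_center(d)
  ss_total <- sum(diag(G))
  df_total <- n - 1L

  # cumulative designs: term k's SS is the trace gain when it enters
  hats <- vector("list", length(terms) + 1L)
  hats[[1L]] <- .hat(.design_for_terms(factors, character(0)))
  for (k in seq_along(terms))
    hats[[k + 1L]] <- .hat(.design_for_terms(factors, terms[seq_len(k)]))
  df <- diff(vapply(hats, `[[`, integer(1), "rank"))
  if (any(df == 0L))
    stop("term(s) with zero degrees of freedom: ",
         paste(terms[df == 0L], collapse = ", "))
  H_full <- hats[[length(hats)]]$H
  rank_full <- hats[[length(hats)]]$rank
  df_res <- n - rank_full
  if (df_res == 0L)
    stop("residual degrees of freedom are zero; the highest-order term is ",
         "confounded with the residual for this design - drop it")

  Hdiff <- lapply(seq_along(terms), function(k) hats[[k + 1L]]$H - hats[[k]]$H)
  ss_term <- vapply(Hdiff, function(Hd) sum(Hd * G), numeric(1))
  ss_res <- ss_total - sum(H_full * G)
  ms_term <- ss_term / df
  ms_res <- ss_res / df_res
  degenerate <- ss_total < 1e-12 * n

  f_obs <- if (degenerate) rep(NA_real_, length(terms)) else ms_term / ms_res

  p_perm <- rep(NA_real_, length(terms))
  perms_used <- rep(NA_integer_, length(terms))
  exhaustive <- factorial(n) <= n_perm

  if (!degenerate) {
    if (exhaustive) {
      P <- .all_perms(n)
    } else {
      if (!is.null(seed)) set.seed(seed)
      P <- t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    }
    tol <- 1e-8 * pmax(1, abs(f_obs))
    term_vars <- lapply(strsplit(terms, ":", fixed = TRUE), sort)
    for (k in seq_along(terms)) {
      # reduced model: every term not containing the tested one (a term the
      # tested term is marginal to would smuggle its effect into the
      # "residuals" being permuted)
      keep <- vapply(seq_along(terms), function(j)
        j != k && !all(term_vars[[k]] %in% term_vars[[j]]), logical(1))
      red <- .hat(.design_for_terms(factors, terms[keep]))
      H_red <- red$H
      intercept_only <- red$rank == 1L
      R_red <- diag(n) - H_red
      exceed <- 0L
      for (i in seq_len(nrow(P))) {
        p <- P[i, ]
        if (intercept_only) {
          # centering is permutation-invariant, so Freedman-Lane collapses to
          # plain relabelling of G
          Gs <- G[p, p]
          tr_gs <- ss_total
        } else {
          M <- H_red + R_red[p, , drop = FALSE]
          Gs <- M %*% G %*% t(M)
          tr_gs <- sum(diag(Gs))
        }
        ss_k <- sum(Hdiff[[k]] * Gs)
        ss_r <- tr_gs - sum(H_full * Gs)
        f_star <- (ss_k / df[k]) / (ss_r / df_res)
        if (f_star >= f_obs[k] - tol[k]) exceed <- exceed + 1L
      }
      if (exhaustive) {
        p_perm[k] <- exceed / nrow(P)          # identity permutation included
        perms_used[k] <- nrow(P)
      } else {
        p_perm[k] <- (1 + exceed) / (1 + n_perm)
        perms_used[k] <- n_perm
      }
    }
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, df_total),
    SS = c(ss_term, ss_res, ss_total),
    MS = c(ms_term, ms_res, NA_real_),
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    p_perm = c(p_perm, NA_real_, NA_real_),
    perms = c(perms_used, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE)
  attr(out, "exhaustive") <- exhaustive
  attr(out, "degenerate") <- degenerate
  class(out) <- c("permanova_table", class(out))
  out
}

#' @export
print.permanova_table <- function(x, ...) {
  cat("PERMANOVA (sequential SS, reduced-model residual permutation)\n")
  if (isTRUE(attr(x, "degenerate")))
    cat("NOTE: all rows identical - tests undefined\n")
  if (isTRUE(attr(x, "exhaustive")))
    cat("NOTE: exhaustive enumeration of all distinct permutations (exact p)\n")
  print.data.frame(cbind(x["term"], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}
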