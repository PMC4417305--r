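#' Gini impurity of a two-class node
#'
#' `1 - p_a^2 - p_b^2` for class counts `n_a`, `n_b`; 0 for an empty
#' node. Vectorised over its arguments.
#'
#' @param n_a,n_b Non-negative class counts.
#' @return Impurity in `[0, 0.5]`.
#' @export
gini_impurity <- function(n_a, n_b) {
  n <- n_a + n_b
  ifelse(n == 0, 0, 1 - (n_a / n)^2 - (n_b / n)^2)
}

#' Fit a single Gini decision stump on a substitution rate
#'
#' Learns the rate threshold that best separates two methylation
#' classes (typically sperm HM vs LM CGIs) with a single CART-style
#' split on Gini impurity. Candidate thresholds are the midpoints
#' between consecutive distinct sorted rate values; the candidate
#' minimising the size-weighted Gini impurity of the two children is
#' returned, with ties broken toward the smallest threshold. The left
#' child holds observations with `rate >= threshold` and the right
#' child `rate < threshold`.
#'
#' @param rate Numeric vector of per-CGI rates (NA dropped with their
#'   labels).
#' @param label Class labels, coercible to a factor with exactly two
#'   observed levels for a non-degenerate fit.
#' @param min_leaf Minimum number of observations per leaf for a
#'   candidate split to be considered (default 1).
#' @return An object of class `cgi_stump` with components `threshold`,
#'   `counts` (2x2 matrix, rows `ge_threshold`/`lt_threshold`, columns
#'   the class levels), `root` (class totals), `weighted_gini`,
#'   `root_gini`, `majority` (per-leaf majority label), `degenerate`,
#'   `n`, `call`. When fewer than two distinct rates or only one class
#'   is present the fit is degenerate: `threshold` is `NA` and
#'   `degenerate` is `TRUE`.
#' @seealso [leaf_composition()], [predict.cgi_stump()]
#' @export
fit_stump <- function(rate, label, min_leaf = 1L) {
  cl <- match.call()
  keep <- !is.na(rate) & !is.na(label)
  rate <- rate[keep]
  label <- factor(label[keep])
  lev <- levels(label)
  root <- table(label)
  root_gini <- if (length(lev) == 2L) gini_impurity(root[[1L]], root[[2L]]) else 0
  degenerate <- function() {
    structure(list(threshold = NA_real_,
                   counts = NULL, root = root,
                   weighted_gini = NA_real_, root_gini = root_gini,
                   majority = NULL, degenerate = TRUE,
                   n = length(rate), call = cl),
              class = "cgi_stump")
  }
  if (length(lev) != 2L || length(unique(rate)) < 2L) return(degenerate())

  ord <- order(rate)
  r <- rate[ord]
  y <- label[ord]
  n <- length(r)
  ## cumulative class counts below each candidate cut (after item i)
  c1 <- cumsum(y == lev[1L])
  c2 <- cumsum(y == lev[2L])
  last_of_value <- which(r[-n] != r[-1L])  # cut between distinct values
  if (length(last_of_value) == 0L) return(degenerate())
  thr <- (r[last_of_value] + r[last_of_value + 1L]) / 2
  n_lo <- last_of_value
  n_hi <- n - n_lo
  ok <- n_lo >= min_leaf & n_hi >= min_leaf
  if (!any(ok)) return(degenerate())
  g_lo <- gini_impurity(c1[last_of_value], c2[last_of_value])
  g_hi <- gini_impurity(c1[n] - c1[last_of_value], c2[n] - c2[last_of_value])
  wg <- (n_lo * g_lo + n_hi * g_hi) / n
  wg[!ok] <- Inf
  best <- which.min(wg)  # ties -> first = smallest threshold
  threshold <- thr[best]
  left <- c(c1[n] - c1[last_of_value[best]], c2[n] - c2[last_of_value[best]])
  right <- c(c1[last_of_value[best]], c2[last_of_value[best]])
  counts <- rbind(ge_threshold = left, lt_threshold = right)
  colnames(counts) <- lev
  majority <- apply(counts, 1L, function(x) lev[which.max(x)])
  structure(list(threshold = threshold, counts = counts, root = root,
                 weighted_gini = wg[best], root_gini = root_gini,
                 majority = majority, degenerate = FALSE,
                 n = n, call = cl),
            class = "cgi_stump")
}

#' Build a stump object from known leaf counts
#'
#' Constructs a `cgi_stump` from an externally determined threshold and
#' per-leaf class counts, e.g. to replay a published split when the
#' underlying per-CGI data are not at hand.
#'
#' @param threshold The split threshold (left leaf: rate >= threshold).
#' @param left,right Named two-element class-count vectors for the
#'   `ge_threshold` and `lt_threshold` leaves (same names, same order).
#' @return A `cgi_stump` object.
#' @export
stump_from_counts <- function(threshold, left, right) {
  if (!identical(names(left), names(right)) || length(left) != 2L)
    .stopf("left/right must be two-element vectors with identical names")
  counts <- rbind(ge_threshold = left, lt_threshold = right)
  root <- left + right
  n <- sum(root)
  wg <- (sum(left) * gini_impurity(left[[1L]], left[[2L]]) +
         sum(right) * gini_impurity(right[[1L]], right[[2L]])) / n
  majority <- apply(counts, 1L, function(x) names(left)[which.max(x)])
  structure(list(threshold = threshold, counts = counts,
                 root = stats::setNames(as.vector(root), names(left)),
                 weighted_gini = wg,
                 root_gini = gini_impurity(root[[1L]], root[[2L]]),
                 majority = majority, degenerate = FALSE,
                 n = n, call = match.call()),
            class = "cgi_stump")
}

#' Per-leaf majority composition of a stump
#'
#' @param fit A non-degenerate `cgi_stump`.
#' @return data.frame with one row per leaf: `leaf`, `n`,
#'   `majority_label`, `fraction` (majority count over leaf size).
#' @export
leaf_composition <- function(fit) {
  stopifnot(inherits(fit, "cgi_stump"))
  if (fit$degenerate) .stopf("degenerate stump has no leaves")
  n_leaf <- rowSums(fit$counts)
  data.frame(
    leaf = rownames(fit$counts),
    n = as.vector(n_leaf),
    majority_label = as.vector(fit$majority),
    fraction = as.vector(apply(fit$counts, 1L, max) / n_leaf),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cgi_stump <- function(x, ...) {
  cat("Single Gini decision stump\n")
  if (x$degenerate) {
    cat(sprintf("  degenerate fit (n = %d): threshold undefined\n", x$n))
    return(invisible(x))
  }
  lev <- colnames(x$counts)
  cat(sprintf("  root: n = %d (%s)  gini = %.4f\n", x$n,
              paste(sprintf("%s: %d", lev, x$root[lev]), collapse = ", "),
              x$root_gini))
  cat(sprintf("  threshold: rate >= %.6g -> left leaf\n", x$threshold))
  for (leaf in rownames(x$counts)) {
    cnt <- x$counts[leaf, ]
    cat(sprintf("  %s: n = %d (%s)  majority %s (%.1f%%)\n", leaf, sum(cnt),
                paste(sprintf("%s: %d", lev, cnt), collapse = ", "),
                x$majority[leaf], 100 * max(cnt) / sum(cnt)))
  }
  cat(sprintf("  weighted gini = %.4f\n", x$weighted_gini))
  invisible(x)
}

#' @export
summary.cgi_stump <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    cat("\nLeaf composition:\n")
    print(leaf_composition(object), row.names = FALSE)
  }
  invisible(object)
}

#' Threshold of a fitted stump
#' @param object A `cgi_stump`.
#' @param ... Unused.
#' @return Named numeric: the fitted threshold.
#' @export
coef.cgi_stump <- function(object, ...) c(threshold = object$threshold)

#' Predict leaf membership or class from a fitted stump
#'
#' @param object A non-degenerate `cgi_stump`.
#' @param newdata Numeric vector of rates.
#' @param type `"leaf"` for `ge_threshold`/`lt_threshold` membership,
#'   `"label"` for the leaf's majority class.
#' @param ... Unused.
#' @return Factor of leaf names or class labels; `NA` rates map to `NA`.
#' @export
predict.cgi_stump <- function(object, newdata, type = c("leaf", "label"), ...) {
  type <- match.arg(type)
  if (object$degenerate) .stopf("cannot predict from a degenerate stump")
  leaf <- ifelse(is.na(newdata), NA_character_,
                 ifelse(newdata >= object$threshold, "ge_threshold", "lt_threshold"))
  if (type == "leaf") return(factor(leaf, levels = rownames(object$counts)))
  factor(unname(object$majority[leaf]), levels = colnames(object$counts))
}
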