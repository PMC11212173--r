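# Jenks natural-breaks classification by exact dynamic programming:
# minimises the total within-class sum of squared deviations over all ways
# of cutting the sorted values into k contiguous classes.

# within-class SSD of sorted values v[i..j] from prefix sums
ssd_range <- function(S1, S2, i, j) {
  s1 <- S1[j + 1] - S1[i]
  s2 <- S2[j + 1] - S2[i]
  m <- j - i + 1
  s2 - s1^2 / m
}

#' Optimal Jenks natural breaks
#'
#' Exact dynamic programming over the sorted values, minimising total
#' within-class SSD. On cost ties the split with the smaller upper bounds
#' is kept. Returns the k class upper bounds (ascending; the last equals
#' the data maximum).
#'
#' @param values numeric vector with at least \code{k} distinct finite
#'   values.
#' @param k number of classes (>= 1).
#' @return numeric vector of k ascending upper bounds, with attribute
#'   \code{ssd} (the optimal total within-class SSD).
#' @export
jenks_breaks <- function(values, k) {
  v <- sort(values[is.finite(values)])
  n <- length(v)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (length(unique(v)) < k) {
    stop(sprintf("need at least k = %d distinct finite values, have %d",
                 k, length(unique(v))), call. = FALSE)
  }
  S1 <- c(0, cumsum(v))
  S2 <- c(0, cumsum(v^2))
  # cost[c, j]: minimal SSD of splitting v[1..j] into c classes
  cost <- matrix(Inf, k, n)
  splitat <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ssd_range(S1, S2, 1, j)
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:n) {
        best <- Inf; bi <- 0L
        for (i in (c - 1):(j - 1)) {
          cc <- cost[c - 1, i] + ssd_range(S1, S2, i + 1, j)
          if (cc < best - 1e-12) { best <- cc; bi <- i }
        }
        cost[c, j] <- best
        splitat[c, j] <- bi
      }
    }
  }
  ends <- integer(k)
  j <- n
  for (c in k:1) {
    ends[c] <- j
    j <- if (c > 1) splitat[c, j] else 0L
  }
  structure(v[ends], ssd = cost[k, n])
}

#' Goodness-of-variance fit of a break set
#'
#' GVF = 1 - within-class SSD / total SSD, in [0, 1].
#'
#' @param values numeric vector.
#' @param breaks ascending class upper bounds covering the data maximum.
#' @return the GVF.
#' @export
gvf <- function(values, breaks) {
  v <- values[is.finite(values)]
  cls <- findInterval(v, breaks, left.open = TRUE) + 1L
  cls[v <= breaks[1]] <- 1L
  ssd_w <- sum(tapply(v, cls, function(x) sum((x - mean(x))^2)))
  ssd_t <- sum((v - mean(v))^2)
  if (ssd_t == 0) return(1)
  1 - ssd_w / ssd_t
}

#' Classify districts by modern-use percent with Jenks natural breaks
#'
#' Five classes by default. Districts with missing or zero percent use go
#' into the lowest class (the "0 / no data" class); remaining positive
#' values are Jenks-classified into the other classes, the top class's
#' upper bound equalling the data maximum. When there are fewer distinct
#' positive values than value classes, the classification uses as many as
#' the data supports, aligned to the top class. With no missing/zero
#' districts all k classes are value classes.
#'
#' @param district_values data.frame with \code{district_id} and
#'   \code{value} (percent use; NA for no data).
#' @param k total number of classes (default 5).
#' @return object of class \code{jenks_result}: \code{k}, \code{breaks}
#'   (upper bounds of the value classes), \code{assignments}
#'   (district_id, value, class), \code{gvf}.
#' @export
classify_districts <- function(district_values, k = 5) {
  stopifnot(is.data.frame(district_values),
            all(c("district_id", "value") %in% names(district_values)))
  val <- district_values$value
  zero_or_na <- is.na(val) | val == 0
  if (all(zero_or_na)) stop("no districts with positive values", call. = FALSE)
  pos <- val[!zero_or_na]
  n_value_classes <- if (any(zero_or_na)) k - 1L else k
  m <- min(n_value_classes, length(unique(pos)))
  br <- jenks_breaks(pos, m)
  first_class <- k - m + 1L
  cls <- rep(NA_integer_, length(val))
  cls[zero_or_na] <- 1L
  pc <- findInterval(pos, br, left.open = TRUE) + 1L
  pc[pc > m] <- m   # top bound equals the max; guard fp comparisons
  cls[!zero_or_na] <- first_class + pc - 1L
  structure(list(
    k = k, breaks = as.numeric(br),
    assignments = data.frame(district_id = district_values$district_id,
                             value = val, class = cls,
                             stringsAsFactors = FALSE),
    gvf = gvf(pos, br)), class = "jenks_result")
}

#' @export
print.jenks_result <- function(x, ...) {
  cat(sprintf("Jenks classification into %d classes (GVF %.3f)\n", x$k, x$gvf))
  cat("  value-class upper bounds:", paste(round(x$breaks, 3), collapse = ", "),
      "\n")
  print(table(class = x$assignments$class))
  invisible(x)
}
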