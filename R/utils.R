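#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# let data.table recognize this package's [.data.table calls as
# data.table-aware (required when running from the installed namespace)
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vf <- function(..., class = "ventriflow_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_vf(name, " must be a finite number", class = "ventriflow_validation_error")
  if (x < lower || (strict_lower && x <= lower))
    stop_vf(name, " must be ", if (strict_lower) "> " else ">= ", lower,
            " (got ", x, ")", class = "ventriflow_validation_error")
  if (x > upper || (strict_upper && x >= upper))
    stop_vf(name, " must be ", if (strict_upper) "< " else "<= ", upper,
            " (got ", x, ")", class = "ventriflow_validation_error")
  invisible(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize_rows <- function(m) m / pmax(row_norms(m), .Machine$double.xmin)

unit <- function(v) v / sqrt(sum(v * v))

#' Rotation matrix mapping the z axis onto a given direction
#' @param axis length-3 direction vector (need not be normalized)
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_to_axis <- function(axis) {
  a <- unit(axis)
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3], z[1] * a[2] - z[2] * a[1])
  c_ <- sum(z * a)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# scatter-add: accumulate values into an n-vector at (possibly repeated) indices
scatter_add <- function(idx, values, n) {
  out <- numeric(n)
  tmp <- rowsum(values, group = idx, reorder = FALSE)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}
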