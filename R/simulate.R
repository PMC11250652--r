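# Synthetic low-Tucker-rank data, uniform missing masks, RSE, and the
# benchmark grid runner.

#' Generate an exact low-Tucker-rank tensor
#'
#' Draws a core tensor of shape `rank` and factor matrices `I_i x R_i`
#' with i.i.d. standard-normal entries and returns their Tucker product
#' `C x_1 U_1 ... x_N U_N`.  The result has Tucker rank `rank` almost
#' surely (the factors are generic, not orthonormalized).
#'
#' @param shape integer vector of tensor extents.
#' @param rank integer vector of Tucker ranks, `rank[i] <= shape[i]`.
#' @param seed integer seed; the draw is fully reproducible.
#' @return a numeric array of dimension `shape`.
#' @export
random_tucker_tensor <- function(shape, rank, seed) {
  shape <- as.integer(shape)
  rank <- as.integer(rank)
  if (length(rank) != length(shape))
    stop_shape("`rank` must have one entry per mode")
  if (any(rank > shape))
    stop_shape("rank (%s) exceeds shape (%s)",
               paste(rank, collapse = ","), paste(shape, collapse = ","))
  with_seed(seed, {
    core <- array(rnorm(prod(rank)), rank)
    factors <- lapply(seq_along(shape), function(i) {
      matrix(rnorm(shape[i] * rank[i]), shape[i])
    })
    multi_mode_product(core, factors)
  })
}

#' Sample a uniform observation mask at an exact missing rate
#'
#' Selects exactly `M = round((1 - mr) * prod(shape))` observed positions
#' uniformly at random without replacement, so the achieved missing rate
#' differs from the target by less than one entry.
#'
#' @param shape integer vector of tensor extents.
#' @param mr target missing rate in `[0, 1)`.
#' @param seed integer seed.
#' @return a logical array of dimension `shape`; `TRUE` marks observed.
#' @export
sample_mask <- function(shape, mr, seed) {
  shape <- as.integer(shape)
  if (length(mr) != 1L || !is.finite(mr) || mr < 0 || mr >= 1)
    stop_shape("`mr` must be a single value in [0, 1)")
  n <- prod(shape)
  m <- round((1 - mr) * n)
  mask <- array(FALSE, shape)
  idx <- with_seed(seed, sample.int(n, m))
  mask[idx] <- TRUE
  mask
}

#' Relative squared error (RSE)
#'
#' `||x - t||_F / ||t||_F` between a recovered tensor and the truth.
#'
#' @param x recovered tensor.
#' @param t true tensor, with `fnorm(t) > 0`.
#' @return a nonnegative scalar.
#' @export
rse <- function(x, t) {
  if (!identical(dim(x), dim(t)))
    stop_shape("`x` and `t` must have identical shapes")
  denom <- fnorm(t)
  if (denom == 0) stop_shape("true tensor has zero norm; RSE undefined")
  fnorm(x - t) / denom
}

#' Run a synthetic completion benchmark grid
#'
#' For each grid cell (shape, rank, missing rate) and each replicate:
#' generate an exact low-Tucker-rank tensor, sample a uniform mask, run
#' [ctnm_qr()], and record the RSE against the known truth and the
#' iteration count.  Replicate r of every cell uses seed
#' `seed_base + r`, so each cell is independently reproducible.  A
#' solver failure in one replicate is recorded and the run continues.
#'
#' @param grid a data frame (or tibble) with list-columns or vectors
#'   `shape`, `rank` (integer vectors per row, as lists) and numeric
#'   `mr`; see the example.
#' @param replicates replicates per cell (default 10).
#' @param config a [solver_config()] template; its `rank` and `seed` are
#'   overridden per cell/replicate.
#' @param seed_base integer; replicate r uses `seed_base + r`.
#' @return a tibble of class `"ctnm_benchmark"`, one row per cell:
#'   `shape`, `rank`, `mr`, `replicates`, `mean_rse`, `mean_iterations`,
#'   `failures`, `seed_base`, plus a list-column `detail` holding the
#'   per-replicate tibble (seed, rse, iterations, stop_reason, error).
#' @examples
#' grid <- tibble::tibble(shape = list(c(15, 15, 15)),
#'                        rank  = list(c(2, 2, 2)),
#'                        mr    = 0.3)
#' run_benchmark(grid, replicates = 2,
#'               config = solver_config(rank = c(2, 2, 2)), seed_base = 7)
#' @export
run_benchmark <- function(grid, replicates = 10L,
                          config = NULL, seed_base = 0L) {
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_shape("`replicates` must be >= 1")
  seed_base <- as.integer(seed_base)
  grid <- tibble::as_tibble(grid)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    shape <- unlist(grid$shape[[cell]])
    rank <- unlist(grid$rank[[cell]])
    mr <- grid$mr[[cell]]
    cfg <- if (is.null(config)) solver_config(rank = rank) else config
    detail <- lapply(seq_len(replicates), function(r) {
      seed <- seed_base + r
      cfg_r <- cfg
      cfg_r$rank <- as.integer(rank)
      cfg_r$seed <- as.integer(seed)
      res <- tryCatch({
        truth <- random_tucker_tensor(shape, rank, seed = seed)
        mask <- sample_mask(shape, mr, seed = seed + 500000L)
        fit <- ctnm_qr(truth, mask, cfg_r)
        tibble::tibble(replicate = r, seed = seed,
                       rse = rse(fit$completed, truth),
                       iterations = fit$iterations,
                       stop_reason = fit$stop_reason,
                       error = NA_character_)
      }, error = function(e) {
        tibble::tibble(replicate = r, seed = seed, rse = NA_real_,
                       iterations = NA_integer_,
                       stop_reason = NA_character_,
                       error = conditionMessage(e))
      })
      res
    })
    detail <- dplyr::bind_rows(detail)
    tibble::tibble(
      shape = paste(shape, collapse = "x"),
      rank = paste(rank, collapse = "x"),
      mr = mr,
      replicates = replicates,
      mean_rse = mean(detail$rse, na.rm = TRUE),
      mean_iterations = mean(detail$iterations, na.rm = TRUE),
      failures = sum(!is.na(detail$error)),
      seed_base = seed_base,
      detail = list(detail)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ctnm_benchmark", class(out))
  out
}

#' Write benchmark results to CSV (summary) and JSON (full detail)
#'
#' @param results a tibble from [run_benchmark()].
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return `results`, invisibly.
#' @export
write_benchmark <- function(results, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    flat <- results[setdiff(names(results), "detail")]
    write.csv(flat, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(results)
}
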