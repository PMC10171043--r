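# Batch exploration of the leaflet design space: sampling over parameter
# ranges, per-design generate -> simulate -> analyze, filtering, quartile
# summaries and per-size selection of "optimal" designs.

#' Sample leaflet designs from parameter ranges
#'
#' Independent uniform draws per parameter (deterministic for a given
#' seed).  The angular span `Sec` is held fixed at 119 degrees unless
#' overridden.
#'
#' @param n Number of designs (>= 1).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param ranges Named list of `c(lower, upper)` ranges for `H1`, `phi`,
#'   `R`, `Rin`, `T`; default [default_ranges()].
#' @param Sec Fixed angular span (degrees), default 119.
#' @return A list of `n` [leaflet_params()] objects.
#' @export
sample_designs <- function(n, seed = 1L, ranges = default_ranges(),
                           Sec = 119) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  need <- c("H1", "phi", "R", "Rin", "T")
  if (!all(need %in% names(ranges))) {
    stop("ranges must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (nm in need) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || !all(is.finite(rg)) || rg[1L] > rg[2L]) {
      stop("invalid (inverted?) range for '", nm, "'", call. = FALSE)
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draws <- lapply(need, function(nm) {
    stats::runif(n, ranges[[nm]][1L], ranges[[nm]][2L])
  })
  names(draws) <- need
  lapply(seq_len(n), function(i) {
    leaflet_params(H1 = draws$H1[i], phi = draws$phi[i], R = draws$R[i],
                   Rin = draws$Rin[i], T = draws$T[i], Sec = Sec)
  })
}

#' Run a batch of leaflet designs
#'
#' For each design: generate the mesh, simulate the opening phase, and
#' compute the evaluation metrics.  Failures (validation errors or solver
#' divergence) are captured per design and recorded with
#' `status = "diverged"`, never dropped.  Results are keyed by `design_id`
#' and independent of evaluation order and worker count (each design is a
#' pure function of its inputs).
#'
#' @param designs List of [leaflet_params()] (or coercible lists).
#' @param fit A [material_fit()], default [default_material()].
#' @param wf A [pressure_waveform()].
#' @param config A [solver_config()].
#' @param nu,ntheta Mesh resolution per design.
#' @param resolution Raster resolution for the projected area (mm/pixel).
#' @param sigma_lim Ultimate strength for the loss index (MPa).
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return A data frame with one row per design: the parameters, the
#'   metrics (`do_percent`, `vm_mean`, `vm_max`, `vm_sd`, `li`) and
#'   `status` (`"ok"` or `"diverged"`).
#' @export
run_batch <- function(designs, fit = default_material(),
                      wf = pressure_waveform(), config = solver_config(),
                      nu = 9, ntheta = 17, resolution = 0.05,
                      sigma_lim = 11.6, workers = 1L) {
  one <- function(i) {
    par <- designs[[i]]
    row <- tryCatch({
      if (!inherits(par, "leaflet_params")) {
        par <- do.call(leaflet_params, as.list(par))
      }
      mesh <- generate_leaflet_mesh(par, nu = nu, ntheta = ntheta)
      sim <- suppressWarnings(run_opening(mesh, fit, wf, config))
      met <- analyze_opening(sim, sigma_lim = sigma_lim,
                             resolution = resolution)
      cbind(data.frame(design_id = i), as.data.frame(par), met,
            data.frame(status = "ok"))
    }, error = function(e) {
      p <- tryCatch(as.data.frame(do.call(leaflet_params, as.list(par))),
                    error = function(e2) {
                      d <- as.list(par)
                      data.frame(H1 = d$H1 %||% NA, phi = d$phi %||% NA,
                                 R = d$R %||% NA, Rin = d$Rin %||% NA,
                                 T = d$T %||% NA, Sec = d$Sec %||% NA)
                    })
      cbind(data.frame(design_id = i), p,
            data.frame(do_percent = NA_real_, vm_mean = NA_real_,
                       vm_max = NA_real_, vm_sd = NA_real_, li = NA_real_,
                       status = "diverged"))
    })
    row
  }
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(designs), one, mc.cores = workers)
  } else {
    lapply(seq_along(designs), one)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter designs by opening and stress thresholds
#'
#' Keeps successfully simulated designs whose degree of opening exceeds
#' `do_min` and whose peak von Mises stress stays below `vm_max_lim`
#' (order-preserving).
#'
#' @param records Data frame from [run_batch()].
#' @param do_min Minimum degree of opening (percent), default 80.
#' @param vm_max_lim Peak stress ceiling (MPa), default 11.6 (the ultimate
#'   strength of pericardium); 4 MPa is the conservative margin used for
#'   the final selection.
#' @return The surviving rows, in their original order.
#' @export
filter_designs <- function(records, do_min = 80, vm_max_lim = 11.6) {
  keep <- records$status == "ok" &
    !is.na(records$do_percent) & records$do_percent > do_min &
    !is.na(records$vm_max) & records$vm_max < vm_max_lim
  records[which(keep), , drop = FALSE]
}

#' Quartile summaries of a batch metric
#'
#' Splits the successfully simulated records into four rank-based quartile
#' groups by the requested metric and reports the quartile boundaries and
#' per-group mean and SD.  By construction the top group's mean is at
#' least the overall mean.
#'
#' @param records Data frame from [run_batch()].
#' @param metric Column to summarise, default `"do_percent"`.
#' @return A list with `boundaries` (25/50/75 % quantiles), `overall_mean`,
#'   and a data frame `quartiles` (`group`, `lower`, `upper`, `n`, `mean`,
#'   `sd`).
#' @export
quartile_stats <- function(records, metric = "do_percent") {
  x <- records[records$status == "ok", metric]
  x <- x[is.finite(x)]
  if (length(x) < 4L) {
    stop("need at least 4 successful records for quartile statistics",
         call. = FALSE)
  }
  bounds <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  grp <- ceiling(4 * rank(x, ties.method = "first") / length(x))
  qdf <- do.call(rbind, lapply(1:4, function(q) {
    xi <- x[grp == q]
    data.frame(group = paste0("Q", q), lower = min(xi), upper = max(xi),
               n = length(xi), mean = mean(xi), sd = stats::sd(xi))
  }))
  list(metric = metric, boundaries = bounds, overall_mean = mean(x),
       quartiles = qdf)
}

#' Select the optimal design for a prosthesis size
#'
#' Applies the opening/stress filter, restricts to designs whose `Rin`
#' lies within `rin_tol` of the target, and returns the record with the
#' smallest loss index.  Ties are broken by higher degree of opening, then
#' lower peak stress, then `design_id`.
#'
#' @param records Data frame from [run_batch()].
#' @param rin_target Target prosthesis radius (mm).
#' @param rin_tol Half-width of the Rin window (mm), default 0.5.
#' @param do_min,vm_max_lim Filter thresholds (see [filter_designs()]).
#' @return The selected one-row data frame.
#' @export
select_optimal <- function(records, rin_target, rin_tol = 0.5,
                           do_min = 80, vm_max_lim = 11.6) {
  ok <- filter_designs(records, do_min = do_min, vm_max_lim = vm_max_lim)
  win <- ok[abs(ok$Rin - rin_target) <= rin_tol, , drop = FALSE]
  if (nrow(win) == 0L) {
    cand <- records[records$status == "ok", , drop = FALSE]
    near <- cand[order(abs(cand$Rin - rin_target)), , drop = FALSE]
    near <- utils::head(near, 3L)
    stop("no filtered design with |Rin - ", rin_target, "| <= ", rin_tol,
         "; nearest candidates (by Rin): ",
         paste(sprintf("id %d (Rin %.2f, DO %.1f%%, vm_max %.2f)",
                       near$design_id, near$Rin, near$do_percent,
                       near$vm_max), collapse = "; "),
         call. = FALSE)
  }
  ord <- order(win$li, -win$do_percent, win$vm_max, win$design_id)
  win[ord[1L], , drop = FALSE]
}
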