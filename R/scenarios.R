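#' List the reference simulation scenarios
#'
#' The catalogue mirrors the model's reference numerical experiments:
#' chemotherapy alone under the three schedules (`fig1a`--`fig1c`),
#' virotherapy alone across replication rates and burst sizes
#' (`fig2a`--`fig2d`), the combination treatment at low and high burst
#' sizes under each schedule (`fig3-caption-*` with b = 2 and 5 as in
#' the panel captions, `fig3-text-*` with b = 15 and 25 as in the
#' accompanying discussion), and the delayed combination model
#' (`fig4a`--`fig4d`).
#'
#' @return A data frame with scenario `id` and `description`.
#' @export
list_scenarios <- function() {
  ids <- names(scenario_builders())
  data.frame(
    id = ids,
    description = vapply(ids, function(i) attr(scenario_builders()[[i]],
                                               "desc"), ""),
    row.names = NULL)
}

# The dimensional replication rates quoted for the virotherapy
# experiments (1e-6, 1e-3) are interpreted per cell, i.e. rescaled by
# the carrying capacity (beta_convention = "per-cell"); Table-style
# desk analysis keeps the default per-1e6-cells convention. Both are
# reachable through `beta_convention`.
scenario_params <- function(beta_dim = NULL, b = NULL,
                            beta_convention = "per-1e6-cells") {
  over <- list()
  if (!is.null(beta_dim)) over$beta <- beta_dim
  if (!is.null(b)) over$b <- b
  dp <- do.call(table1_params, over)
  nondimensionalize(dp, beta_convention = beta_convention)
}

scenario_builders <- function() {
  bld <- list()
  add <- function(id, desc, fn) {
    attr(fn, "desc") <- desc
    bld[[id]] <<- fn
  }
  ics_chemo <- c(U = 0.8, C = 0.2)
  for (kind in c("constant", "exponential", "sinusoidal")) {
    id <- paste0("fig1", letters[match(kind, c("constant", "exponential",
                                               "sinusoidal"))])
    local({
      k <- kind
      add(id, paste0("chemotherapy only, ", k, " infusion"),
          function() {
            p <- scenario_params()
            list(model = "chemo", p = p,
                 spec = infusion_spec(k, phi = p$phi, a = p$a),
                 delays = delay_spec(), y0 = ics_chemo,
                 t_span = c(0, 30), h = 0.001)
          })
    })
  }
  viro_sc <- list(fig2a = c(1e-6, 10), fig2b = c(1e-3, 10),
                  fig2c = c(1e-6, 10), fig2d = c(1e-6, 100))
  for (id in names(viro_sc)) {
    local({
      bv <- viro_sc[[id]]; sid <- id
      add(sid, sprintf("virotherapy only, beta = %g, b = %g", bv[1], bv[2]),
          function() {
            p <- scenario_params(beta_dim = bv[1], b = bv[2],
                                 beta_convention = "per-cell")
            list(model = "viro", p = p, spec = infusion_spec("none"),
                 delays = delay_spec(), y0 = c(U = 1, I = 0, V = 0.1),
                 t_span = c(0, 30), h = 0.001)
          })
    })
  }
  fig3 <- expand.grid(src = c("caption", "text"),
                      kind = c("constant", "exponential", "sinusoidal"),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(fig3))) {
    src <- fig3$src[r]; kind <- fig3$kind[r]
    bs <- if (src == "caption") c(2, 5) else c(15, 25)
    for (b in bs) {
      local({
        s <- src; k <- kind; bb <- b
        add(sprintf("fig3-%s-b%d-%s", s, as.integer(bb), k),
            sprintf("combination treatment, %s infusion, b = %d (%s values)",
                    k, bb, s),
            function() {
              p <- scenario_params(beta_dim = 1e-6, b = bb,
                                   beta_convention = "per-cell")
              list(model = "full", p = p,
                   spec = infusion_spec(k, phi = p$phi, a = p$a),
                   delays = delay_spec(),
                   y0 = c(U = 1, I = 0, V = 0.1, C = 0.1),
                   t_span = c(0, 30), h = 0.001)
            })
      })
    }
  }
  fig4 <- list(fig4a = c(0.001, 0.1), fig4b = c(0.01, 0.1),
               fig4c = c(0.001, 0.001), fig4d = c(0.001, 0.3))
  for (id in names(fig4)) {
    local({
      tv <- fig4[[id]]; sid <- id
      add(sid, sprintf("delayed combination, tau1 = %g, tau2 = %g",
                       tv[1], tv[2]),
          function() {
            p <- scenario_params(beta_dim = 1e-6, b = 10,
                                 beta_convention = "per-cell")
            list(model = "full", p = p,
                 spec = infusion_spec("constant", phi = p$phi, a = p$a),
                 delays = delay_spec(tau1 = tv[1], tau2 = tv[2]),
                 y0 = c(U = 1, I = 0, V = 0.1, C = 0.1),
                 t_span = c(0, 15), h = 0.001)
          })
    })
  }
  bld
}

#' Resolve a scenario id to a runnable configuration
#'
#' @param id A scenario id from [list_scenarios()].
#' @param ... Overrides applied on top of the catalogue entry
#'   (`t_span`, `h`, `y0`, ...).
#' @return An object of class `cv_scenario`.
#' @export
scenario <- function(id, ...) {
  bld <- scenario_builders()
  if (!id %in% names(bld))
    stop("scenario: unknown id '", id, "'; see list_scenarios()")
  cfg <- bld[[id]]()
  cfg$id <- id
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "cv_scenario")
}

#' Run a scenario
#'
#' Integrates the scenario's model (ODE path, or the method-of-steps
#' path when either delay is positive), computes the clearance-time
#' metric, and attaches the equilibrium catalogue and stability
#' reports at the scenario's parameters. Everything is deterministic:
#' re-running a scenario reproduces the trajectory bit for bit.
#'
#' @param s A `cv_scenario` (or scenario id string).
#' @param out_dir Optional directory; when given, writes `traj.csv`
#'   (+ JSON sidecar), `metrics.json`, and `stability.json`.
#' @param threshold Clearance threshold on `U + I` (default 1e-3).
#' @return List with `trajectory`, `clearance`, `equilibria`,
#'   `stability`, `scenario`.
#' @export
run_scenario <- function(s, out_dir = NULL, threshold = 1e-3) {
  if (is.character(s)) s <- scenario(s)
  stopifnot(inherits(s, "cv_scenario"))
  has_delay <- s$delays$tau1 > 0 || s$delays$tau2 > 0
  traj <- tryCatch({
    if (has_delay) {
      simulate_dde(s$model, s$p, s$spec, s$delays, y0 = s$y0,
                   t_span = s$t_span, h = s$h)
    } else {
      simulate_model(s$model, s$p, s$spec, y0 = s$y0,
                     t_span = s$t_span, h = s$h)
    }
  }, error = function(e)
    stop("run_scenario [", s$id, "]: ", conditionMessage(e)))
  cl <- clearance_time(traj, threshold = threshold)
  eq <- if (s$model == "none") list() else
    equilibria(s$model, s$p, s$spec)
  stab <- lapply(Filter(function(x) x$exists, eq),
                 classify, p = s$p, spec = s$spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, file.path(out_dir, "traj.csv"))
    jsonlite::write_json(
      list(scenario = s$id, cleared = cl$cleared, time = cl$time,
           days = cl$days, threshold = threshold),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    jsonlite::write_json(
      list(equilibria = equilibria_report(eq),
           stability = stability_report(stab)),
      file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  list(trajectory = traj, clearance = cl, equilibria = eq,
       stability = stab, scenario = s)
}

#' Compare the three infusion schedules on one base scenario
#'
#' Runs the combination model under constant, exponential, and
#' sinusoidal infusion at the same infusion rate `phi`, and ranks the
#' schedules by terminal tumor burden (`U + I` at the end of the
#' horizon). Also reports clearance times and the cumulative
#' administered drug \eqn{\int_0^T \xi(t)\,dt} (closed forms).
#'
#' @param base A `cv_scenario` (or id) with `model = "full"`.
#' @param threshold Clearance threshold (default 1e-3).
#' @return A data frame, best (lowest terminal burden) first.
#' @export
compare_infusions <- function(base, threshold = 1e-3) {
  if (is.character(base)) base <- scenario(base)
  stopifnot(inherits(base, "cv_scenario"))
  if (base$model != "full")
    stop("compare_infusions: base scenario must use the full model")
  phi <- base$spec$phi; a <- base$spec$a
  Tend <- base$t_span[2]
  rows <- lapply(c("constant", "exponential", "sinusoidal"), function(k) {
    s <- base
    s$spec <- infusion_spec(k, phi = phi, a = a)
    s$id <- paste0(base$id, "-", k)
    res <- run_scenario(s, threshold = threshold)
    st <- res$trajectory$state
    burden <- st[nrow(st), "U"] + st[nrow(st), "I"]
    cum_drug <- switch(k,
      constant = phi * Tend,
      exponential = phi * (1 - exp(-a * Tend)) / a,
      sinusoidal = phi * (Tend / 2 - sin(2 * a * Tend) / (4 * a)))
    data.frame(schedule = k, cleared = res$clearance$cleared,
               clearance_time = res$clearance$time,
               clearance_days = res$clearance$days,
               terminal_burden = burden, cumulative_drug = cum_drug)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$terminal_burden), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a scenario from a YAML or JSON configuration file
#'
#' Expected keys: `model`, `params` (nondimensional rates, see
#' [nondim_params()]), `infusion` (`kind`, `phi`, `a`), optional
#' `delays` (`tau1`, `tau2`), `y0`, `t_span`, `h`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cv_scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_scenario_config: the 'yaml' package is required for YAML")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  p <- do.call(nondim_params, as.list(cfg$params))
  spec <- do.call(infusion_spec, as.list(cfg$infusion))
  delays <- if (!is.null(cfg$delays))
    do.call(delay_spec, as.list(cfg$delays)) else delay_spec()
  y0 <- if (!is.null(cfg$y0)) unlist(cfg$y0) else NULL
  structure(list(id = cfg$id %||% basename(path), model = cfg$model,
                 p = p, spec = spec, delays = delays, y0 = y0,
                 t_span = cfg$t_span %||% c(0, 30), h = cfg$h %||% 0.001),
            class = "cv_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: model=%s, infusion=%s (phi=%g), tau1=%g, tau2=%g\n",
              x$id, x$model, x$spec$kind, x$spec$phi,
              x$delays$tau1, x$delays$tau2))
  invisible(x)
}
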