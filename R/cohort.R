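#' Specification of a synthetic behavioral cohort
#'
#' Describes a group of simulated participants emulating the behavioral
#' study design: 160-trial blocks on the fixed experimental reversal
#' schedule, responses sampled from the softmax response model, and
#' individual parameters drawn on the positive `lambda` scale from
#' log-normal group distributions (the scale on which the hierarchical
#' prior of the fitting machinery lives).
#'
#' Default group centers (native scale): ED-HMM `delta = 0.1`, `r = 2`,
#' `mu0A = 0.8`, `mu0B = 0.2`; DU-RW `alpha = 0.25`, `kappa = 0.7`,
#' `V0 = (0, 0)`; both `beta = 3` (unbounded transform), `bias = 0.5`.
#' Default log-scale spreads are wide for the learning parameters (1.0 and
#' 0.75) to produce clearly heterogeneous temporal beliefs and moderate for
#' the remaining parameters.
#'
#' @param n_subjects Number of simulated participants.
#' @param model Generating model, `"ed_hmm"` or `"du_rw"` (recycled across
#'   subjects; supply a vector for mixed cohorts).
#' @param lambda_center Positive length-6 vector of group medians on the
#'   lambda scale (defaults as above).
#' @param lambda_sd Length-6 vector of log-normal standard deviations.
#' @param schedule A `task_schedule` (default [experimental_schedule()]).
#' @param beta_transform `"positive"` (default) or `"bounded"`.
#' @param d_max,nu0 ED-HMM settings.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 22L, model = "ed_hmm",
                        lambda_center = NULL, lambda_sd = NULL,
                        schedule = experimental_schedule(),
                        beta_transform = c("positive", "bounded"),
                        d_max = 200L, nu0 = 10, seed = 1L) {
  beta_transform <- match.arg(beta_transform)
  model <- rep(model, length.out = n_subjects)
  if (!all(model %in% c("ed_hmm", "du_rw"))) {
    stop("`model` entries must be \"ed_hmm\" or \"du_rw\"")
  }
  defaults <- list(
    ed_hmm = list(center = c(0.1 / 0.9, 1, 4, 4, 3, 1),
                  sd = c(1, 0.75, 0.25, 0.25, 0.3, 0.1)),
    du_rw = list(center = c(1 / 3, 7 / 3, 1, 1, 3, 1),
                 sd = c(1, 0.75, 0.25, 0.25, 0.3, 0.1)))
  structure(
    list(n_subjects = as.integer(n_subjects), model = model,
         lambda_center = lambda_center, lambda_sd = lambda_sd,
         defaults = defaults, schedule = schedule,
         beta_transform = beta_transform, d_max = as.integer(d_max),
         nu0 = nu0, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws each subject's parameters from the group distributions of a
#' [cohort_spec()], simulates a full block of softmax-sampled responses on
#' the schedule, and returns the behavioral data together with the
#' ground-truth parameter table used to generate them.
#'
#' @param spec A [cohort_spec()].
#' @return List with `data` (tidy behavioral data frame across subjects) and
#'   `ground_truth` (one row per subject: generating model, native-scale
#'   parameters, lambda-scale parameters).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 42))
#' head(coh$ground_truth)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  data_list <- vector("list", spec$n_subjects)
  gt <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    model <- spec$model[s]
    center <- if (is.null(spec$lambda_center))
      spec$defaults[[model]]$center else spec$lambda_center
    sds <- if (is.null(spec$lambda_sd)) spec$defaults[[model]]$sd else
      spec$lambda_sd
    lam <- exp(stats::rnorm(6L, mean = log(center), sd = sds))
    native <- transform_parameters(lam, model, spec$beta_transform)
    agent <- agent_from_native(native, model, d_max = spec$d_max,
                               nu0 = spec$nu0)
    id <- sprintf("sub%03d", s)
    res <- run_block(agent, spec$schedule,
                     params = response_params(beta = native$beta,
                                              bias_A = native$bias),
                     mode = "sample", subject = id)
    data_list[[s]] <- res$data
    gt[[s]] <- data.frame(subject = id, model = model,
                          t(unlist(native)),
                          t(stats::setNames(lam, paste0("lambda", 1:6))),
                          performance = res$performance,
                          stringsAsFactors = FALSE)
  }
  list(data = do.call(rbind, data_list),
       ground_truth = rbind_fill(gt))
}

# Row-bind data frames with possibly different columns (mixed-model
# cohorts), padding the missing ones with NA.
rbind_fill <- function(frames) {
  cols <- unique(unlist(lapply(frames, names)))
  do.call(rbind, lapply(frames, function(f) {
    for (m in setdiff(cols, names(f))) f[[m]] <- NA
    f[, cols]
  }))
}

#' Write a cohort to disk
#'
#' Produces one CSV per subject plus a `ground_truth.csv` sidecar in `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in split(cohort$data, cohort$data$subject)) {
    write_behavior_csv(d, file.path(dir, paste0(d$subject[1L], ".csv")))
  }
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
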