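#' Read / write the model configuration
#'
#' YAML file with three sections: \code{remodeler} (slots of
#' \code{\linkS4class{RemodelerParams}}), \code{sequence} (slots of
#' \code{\linkS4class{MappingRules}}) and \code{dynamics} (arguments of
#' \code{\link{integratorConfig}} plus the schedule phase durations).
#' Omitted keys fall back to the shipped defaults, so a config only needs
#' to list overrides.
#'
#' @param path file path.
#' @return \code{readConfig}: list with elements \code{remodeler}
#'   (RemodelerParams), \code{rules} (MappingRules), \code{cfg}
#'   (IntegratorConfig), \code{schedule} (data.frame).
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  rem <- do.call(defaultRemodelerParams, as.paramList(y$remodeler))
  rules <- do.call(defaultMappingRules, y$sequence %||% list())
  dyn <- y$dynamics %||% list()
  cfgArgs <- dyn[intersect(names(dyn), c("dt", "D_dna", "D_lobe", "stride"))]
  cfg <- do.call(integratorConfig, cfgArgs)
  sched <- if (!is.null(dyn$schedule)) {
    schedule(vapply(dyn$schedule, `[[`, "", "chem"),
             vapply(dyn$schedule, function(p) as.numeric(p$duration), 0))
  } else defaultSchedule()
  list(remodeler = rem, rules = rules, cfg = cfg, schedule = sched)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as.paramList <- function(x) {
  if (is.null(x)) return(list())
  if (!is.null(x$epsLobes)) x$epsLobes <- unlist(x$epsLobes)
  if (!is.null(x$epsLobeDna)) x$epsLobeDna <- unlist(x$epsLobeDna)
  x
}

#' @rdname readConfig
#' @param remodeler a \code{\linkS4class{RemodelerParams}}.
#' @param rules a \code{\linkS4class{MappingRules}}.
#' @param cfg an \code{\link{integratorConfig}}.
#' @param sched a \code{\link{schedule}} data.frame.
#' @export
writeConfig <- function(path, remodeler = defaultRemodelerParams(),
                        rules = defaultMappingRules(),
                        cfg = integratorConfig(),
                        sched = defaultSchedule()) {
  slotsOf <- function(obj) {
    nm <- slotNames(class(obj))
    setNames(lapply(nm, function(s) {
      v <- slot(obj, s)
      if (!is.null(names(v))) as.list(v) else v
    }), nm)
  }
  y <- list(
    remodeler = slotsOf(remodeler),
    sequence = slotsOf(rules),
    dynamics = c(unclass(cfg),
                 list(schedule = lapply(seq_len(nrow(sched)), function(i) {
                   list(chem = sched$chem[i], duration = sched$duration[i])
                 }))))
  yaml::write_yaml(y, path)
  invisible(path)
}
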