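#' Load and validate an analyte panel configuration
#'
#' A panel configuration defines every quantified target and internal
#' standard: its ESI mode, internal-standard assignment, conjugate
#' quantification group, calibration range (uM, extract scale) and an
#' optional exclusion flag with reason. The configuration also carries the
#' nominal internal-standard spike per ESI mode and the serial-dilution
#' scheme per matrix. Panels round-trip losslessly through YAML via
#' [write_panel()].
#'
#' @param source Path to a YAML file, or an already-parsed list with the
#'   same structure (`analytes`, `intstd_nominal`, `matrices`,
#'   `dilution_schemes`).
#' @return A `panel_config` object: a list with `analytes` (data frame),
#'   `intstd_nominal` (named numeric, one value per ESI mode),
#'   `matrices` (character) and `dilution_schemes` (named list of
#'   increasing dilution factors).
#' @examples
#' panel <- default_panel()
#' nrow(panel$analytes)  # 32 entries: 30 targets + 2 internal standards
#' @export
load_panel <- function(source) {
  cfg <- if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("panel config file not found: ", source)
    yaml::read_yaml(source)
  } else if (is.list(source)) {
    source
  } else {
    stop("`source` must be a file path or a list")
  }
  for (fld in c("analytes", "intstd_nominal", "matrices", "dilution_schemes")) {
    if (is.null(cfg[[fld]])) stop("panel config is missing field `", fld, "`")
  }

  an <- lapply(cfg$analytes, function(a) {
    for (fld in c("id", "name", "class", "esi_mode", "internal_standard",
                  "calibration_range")) {
      if (is.null(a[[fld]]))
        stop("analyte entry missing field `", fld, "`",
             if (!is.null(a$id)) paste0(" (id ", a$id, ")"))
    }
    cr <- as.numeric(a$calibration_range)
    if (length(cr) != 2L) stop("calibration_range of ", a$id, " must have two values")
    data.frame(
      id = as.character(a$id),
      name = as.character(a$name),
      class = as.character(a$class),
      esi_mode = as.character(a$esi_mode),
      internal_standard = as.character(a$internal_standard),
      conjugate_group = if (is.null(a$conjugate_group)) "none" else as.character(a$conjugate_group),
      cal_low = cr[1], cal_high = cr[2],
      excluded = isTRUE(a$excluded),
      exclusion_reason = if (is.null(a$exclusion_reason)) "" else as.character(a$exclusion_reason),
      is_internal_standard = isTRUE(a$internal_standard_flag),
      stringsAsFactors = FALSE
    )
  })
  an <- do.call(rbind, an)

  if (anyDuplicated(an$id))
    stop("duplicate analyte id(s): ",
         paste(unique(an$id[duplicated(an$id)]), collapse = ", "))
  bad_class <- setdiff(an$class, c("uremic_toxin", "primary_bile_acid", "secondary_bile_acid"))
  if (length(bad_class)) stop("unknown analyte class: ", paste(bad_class, collapse = ", "))
  bad_mode <- setdiff(an$esi_mode, c("positive", "negative"))
  if (length(bad_mode)) stop("unknown esi_mode: ", paste(bad_mode, collapse = ", "))
  if (any(an$cal_low <= 0 | an$cal_high <= 0 | an$cal_low >= an$cal_high))
    stop("calibration_range must satisfy 0 < low < high (offending: ",
         paste(an$id[an$cal_low <= 0 | an$cal_high <= 0 | an$cal_low >= an$cal_high],
               collapse = ", "), ")")
  intstd_ids <- an$id[an$is_internal_standard]
  dangling <- setdiff(an$internal_standard, intstd_ids)
  if (length(dangling))
    stop("internal_standard reference(s) not present in panel: ",
         paste(dangling, collapse = ", "))
  if (any(an$excluded & !nzchar(an$exclusion_reason)))
    stop("excluded analytes must carry a non-empty exclusion_reason: ",
         paste(an$id[an$excluded & !nzchar(an$exclusion_reason)], collapse = ", "))

  nominal <- unlist(cfg$intstd_nominal)
  if (!setequal(names(nominal), c("positive", "negative")) || length(nominal) != 2L)
    stop("intstd_nominal must hold exactly one spike level per ESI mode")
  nominal <- vapply(nominal, as.numeric, numeric(1))
  if (any(nominal <= 0)) stop("intstd_nominal spikes must be positive")

  matrices <- as.character(unlist(cfg$matrices))
  schemes <- lapply(cfg$dilution_schemes, function(d) as.numeric(unlist(d)))
  missing_scheme <- setdiff(matrices, names(schemes))
  if (length(missing_scheme))
    stop("dilution_schemes missing matrix: ", paste(missing_scheme, collapse = ", "))
  for (m in names(schemes)) {
    d <- schemes[[m]]
    if (any(d < 1) || is.unsorted(d, strictly = TRUE))
      stop("dilution factors for ", m, " must be >= 1 and strictly increasing")
  }

  structure(
    list(analytes = an, intstd_nominal = nominal,
         matrices = matrices, dilution_schemes = schemes),
    class = "panel_config"
  )
}

#' The shipped default panel
#'
#' Thirty quantified targets (16 uremic toxins and 14 bile acids) plus the
#' two internal standards (p-CS-d7 for ESI-negative analytes, GDCA-d6 for
#' ESI-positive). Three targets (GCA, CDCA, GB) are flagged excluded
#' because they accumulate on the analytical column; the six co-eluting
#' conjugated bile acids are labelled for collapse into taurine- and
#' glycine-conjugate groups.
#'
#' @return A validated `panel_config`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "default_panel.yaml", package = "gmmquant"))
}

#' Write a panel configuration back to YAML
#'
#' @param panel A `panel_config`.
#' @param path Output file path.
#' @return `path`, invisibly. `load_panel(write_panel(p, f))` reproduces `p`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_config"))
  an <- panel$analytes
  entries <- lapply(seq_len(nrow(an)), function(i) {
    e <- list(
      id = an$id[i], name = an$name[i], class = an$class[i],
      esi_mode = an$esi_mode[i], internal_standard = an$internal_standard[i],
      conjugate_group = an$conjugate_group[i],
      calibration_range = c(an$cal_low[i], an$cal_high[i]),
      excluded = an$excluded[i]
    )
    if (nzchar(an$exclusion_reason[i])) e$exclusion_reason <- an$exclusion_reason[i]
    if (an$is_internal_standard[i]) e$internal_standard_flag <- TRUE
    e
  })
  yaml::write_yaml(
    list(intstd_nominal = as.list(panel$intstd_nominal),
         matrices = panel$matrices,
         dilution_schemes = lapply(panel$dilution_schemes, identity),
         analytes = entries),
    path
  )
  invisible(path)
}

#' Target analytes of a panel
#'
#' @param panel A `panel_config`.
#' @param include_excluded Keep analytes flagged excluded?
#' @return Character vector of analyte ids, internal standards omitted.
#' @export
panel_targets <- function(panel, include_excluded = TRUE) {
  an <- panel$analytes
  keep <- !an$is_internal_standard
  if (!include_excluded) keep <- keep & !an$excluded
  an$id[keep]
}

#' Resolve conjugate quantification groups
#'
#' Co-eluting conjugated bile acids are quantified as summed groups
#' (taurine- and glycine-conjugates); every other retained target maps to a
#' singleton group named after itself. Excluded analytes and internal
#' standards appear in no group. A conjugate label carried by a single
#' panel member is demoted to a singleton with a warning.
#'
#' @param panel A `panel_config`.
#' @return Named list mapping reporting-entity label to member analyte ids.
#'   The union of all groups plus the excluded set equals the target list,
#'   and groups are pairwise disjoint.
#' @examples
#' groups <- resolve_quant_groups(default_panel())
#' groups$taurine_conjugates  # TCDCA, TDCA, TUDCA
#' @export
resolve_quant_groups <- function(panel) {
  stopifnot(inherits(panel, "panel_config"))
  an <- panel$analytes
  an <- an[!an$is_internal_standard & !an$excluded, , drop = FALSE]
  groups <- list()
  for (g in unique(an$conjugate_group[an$conjugate_group != "none"])) {
    members <- an$id[an$conjugate_group == g]
    if (length(members) < 2L) {
      warning("conjugate group `", g, "` has a single member (",
              members, "); treated as singleton")
      an$conjugate_group[an$id == members] <- "none"
    } else {
      groups[[g]] <- members
    }
  }
  singletons <- an$id[an$conjugate_group == "none" |
                        !(an$conjugate_group %in% names(groups))]
  for (s in singletons) groups[[s]] <- s
  groups
}

#' Panel bookkeeping arithmetic
#'
#' Records the panel's own counts: targets, exclusions, conjugate members,
#' collapsed groups and the resulting number of reporting entities. Panel
#' counts reported elsewhere for this assay are not internally consistent,
#' so the package exposes its arithmetic instead of forcing agreement.
#'
#' @param panel A `panel_config`.
#' @return Named list of counts.
#' @export
panel_arithmetic <- function(panel) {
  an <- panel$analytes
  targets <- an[!an$is_internal_standard, , drop = FALSE]
  groups <- resolve_quant_groups(panel)
  list(
    n_entries = nrow(an),
    n_internal_standards = sum(an$is_internal_standard),
    n_targets = nrow(targets),
    n_uremic_toxins = sum(targets$class == "uremic_toxin"),
    n_bile_acids = sum(targets$class != "uremic_toxin"),
    n_excluded = sum(targets$excluded),
    n_conjugate_members = sum(lengths(groups)[lengths(groups) > 1L]),
    n_conjugate_groups = sum(lengths(groups) > 1L),
    n_reporting_entities = length(groups)
  )
}

#' @export
print.panel_config <- function(x, ...) {
  a <- panel_arithmetic(x)
  cat("<panel_config> ", a$n_targets, " targets (",
      a$n_uremic_toxins, " UT, ", a$n_bile_acids, " BA) + ",
      a$n_internal_standards, " internal standards\n",
      "  excluded: ", a$n_excluded,
      "; reporting entities after collapse: ", a$n_reporting_entities, "\n",
      "  matrices: ", paste(x$matrices, collapse = ", "), "\n", sep = "")
  invisible(x)
}
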