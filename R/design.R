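#' Study design for a two-group destructive tissue-distribution study
#'
#' A `study_design` captures everything about the animal experiment that the
#' downstream statistics depend on: which tissues are sampled, which tissues
#' exist only in one sex, the sacrifice time grid, and how many animals are
#' sacrificed per time point in each group. The default values reproduce a
#' rat study with eight tissues (heart, liver, spleen, lung, kidney, uterus,
#' ovary, testes), seven sacrifice times between 10 and 720 minutes, and six
#' animals (three per sex) per time point per group.
#'
#' @param tissues Character vector of tissue identifiers, in reporting order.
#' @param sex_specific Named character vector mapping every tissue to one of
#'   `"both"`, `"female_only"`, `"male_only"`.
#' @param time_points_min Strictly increasing positive sacrifice times, in
#'   minutes after the oral dose.
#' @param animals_per_point_per_group Animals sacrificed per time point per
#'   group (half male, half female); sex-specific tissues therefore yield
#'   half this number of samples.
#' @param groups Character vector of the two treatment group labels.
#' @param dose_volume_per_bw Administered extract volume in mL per 200 g
#'   body weight (recorded for provenance; not used in any computation).
#' @param homogenate_dilution_factor Total homogenate volume per volume of
#'   tissue. Two volumes of saline added to one of tissue gives 3.
#'   Concentrations stay in ng/mL of homogenate throughout; multiply by this
#'   factor only if a per-gram-of-tissue value is wanted.
#'
#' @return An object of class `study_design`.
#' @seealso [load_design()] for reading a design from a YAML file.
#' @export
study_design <- function(tissues = c("heart", "liver", "spleen", "lung",
                                     "kidney", "uterus", "ovary", "testes"),
                         sex_specific = c(heart = "both", liver = "both",
                                          spleen = "both", lung = "both",
                                          kidney = "both",
                                          uterus = "female_only",
                                          ovary = "female_only",
                                          testes = "male_only"),
                         time_points_min = c(10, 30, 90, 180, 360, 480, 720),
                         animals_per_point_per_group = 6L,
                         groups = c("crude", "salt_processed"),
                         dose_volume_per_bw = 1.2,
                         homogenate_dilution_factor = 3) {
  tissues <- as.character(tissues)
  if (anyDuplicated(tissues) > 0L)
    stop("duplicate tissue identifiers in design", call. = FALSE)
  missing_rule <- setdiff(tissues, names(sex_specific))
  if (length(missing_rule) > 0L)
    stop("no sex rule for tissue(s): ", paste(missing_rule, collapse = ", "),
         call. = FALSE)
  sex_specific <- sex_specific[tissues]
  bad <- !sex_specific %in% c("both", "female_only", "male_only")
  if (any(bad))
    stop("invalid sex rule for: ", paste(tissues[bad], collapse = ", "),
         call. = FALSE)
  # anatomy is not configurable: gonadal organs must carry their sex
  for (tt in intersect(c("uterus", "ovary"), tissues))
    if (sex_specific[[tt]] != "female_only")
      stop(tt, " must be female_only", call. = FALSE)
  if ("testes" %in% tissues && sex_specific[["testes"]] != "male_only")
    stop("testes must be male_only", call. = FALSE)

  time_points_min <- as.numeric(time_points_min)
  if (length(time_points_min) < 2L || any(time_points_min <= 0) ||
      any(diff(time_points_min) <= 0))
    stop("time points must be > 0 and strictly increasing", call. = FALSE)
  if (animals_per_point_per_group < 1L)
    stop("animals_per_point_per_group must be >= 1", call. = FALSE)
  if (homogenate_dilution_factor < 1)
    stop("homogenate_dilution_factor must be >= 1", call. = FALSE)
  if (length(groups) != 2L)
    stop("exactly two treatment groups are supported", call. = FALSE)

  structure(list(tissues = tissues,
                 sex_specific = sex_specific,
                 time_points_min = time_points_min,
                 animals_per_point_per_group = as.integer(animals_per_point_per_group),
                 groups = as.character(groups),
                 dose_volume_per_bw = dose_volume_per_bw,
                 homogenate_dilution_factor = homogenate_dilution_factor),
            class = "study_design")
}

#' Read a study design from a YAML file
#'
#' The file may declare any subset of the [study_design()] arguments; omitted
#' keys take the defaults, so an empty file yields the packaged default
#' design. `sex_specific` is a YAML mapping `tissue: rule`.
#'
#' @param path Path to a YAML design file. The packaged default lives at
#'   `system.file("extdata", "default_design.yaml", package = "tissuerte")`.
#' @return A `study_design`.
#' @export
load_design <- function(path = default_design_path()) {
  if (!file.exists(path))
    stop("design file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  args <- list()
  for (key in c("tissues", "time_points_min", "animals_per_point_per_group",
                "groups", "dose_volume_per_bw", "homogenate_dilution_factor"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$sex_specific))
    args$sex_specific <- unlist(cfg$sex_specific)
  if (!is.null(args$tissues) && is.null(args$sex_specific))
    stop("a design declaring tissues must also declare sex_specific rules",
         call. = FALSE)
  do.call(study_design, args)
}

#' @rdname load_design
#' @export
default_design_path <- function() {
  system.file("extdata", "default_design.yaml", package = "tissuerte",
              mustWork = TRUE)
}

#' Number of animals contributing samples of a tissue per time point
#'
#' Sex-specific tissues are collected from half the animals (the matching
#' sex); shared tissues from all of them.
#'
#' @param design A `study_design`.
#' @param tissue Tissue identifier.
#' @return Integer count per time point per group.
#' @export
animals_for_tissue <- function(design, tissue) {
  stopifnot(inherits(design, "study_design"))
  if (!tissue %in% names(design$sex_specific))
    stop("unknown tissue: ", tissue, call. = FALSE)
  rule <- design$sex_specific[[tissue]]
  n <- design$animals_per_point_per_group
  if (rule == "both") n else n %/% 2L
}

#' Sexes in which a tissue is collected
#' @param design A `study_design`.
#' @param tissue Tissue identifier.
#' @return `"M"`, `"F"`, or both.
#' @export
sexes_for_tissue <- function(design, tissue) {
  if (!tissue %in% names(design$sex_specific))
    stop("unknown tissue: ", tissue, call. = FALSE)
  rule <- design$sex_specific[[tissue]]
  switch(rule, both = c("M", "F"), female_only = "F", male_only = "M")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Tissue-distribution study design\n")
  cat("  tissues:     ", paste(x$tissues, collapse = ", "), "\n")
  cat("  time points: ", paste(x$time_points_min, collapse = ", "),
      "min\n")
  cat("  groups:      ", paste(x$groups, collapse = " vs "), "\n")
  cat("  animals/point/group:", x$animals_per_point_per_group,
      "(half per sex)\n")
  invisible(x)
}
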