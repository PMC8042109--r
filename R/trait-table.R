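# Per-species measurement table: one row per species, volumes in mm^3,
# surfaces in mm^2, body mass in grams. Missing measurements are NA and
# propagate; they are never silently replaced by zeros.

LOCOMOTOR_LEVELS <- c("arboreal", "fossorial", "glider", "scansorial",
                      "terrestrial")

TRAIT_COLUMNS <- c("species", "status", "locomotion", "body_mass",
                   "endocranial_volume", "endocranial_surface",
                   "neocortex_surface", "olfactory_bulb_volume",
                   "petrosal_lobule_volume")

#' Assemble and validate a trait table
#'
#' @param df A data.frame with columns `species`, `status`
#'   (`"extant"`/`"extinct"`), `locomotion` (one of arboreal, fossorial,
#'   glider, scansorial, terrestrial), `body_mass` (g),
#'   `endocranial_volume` (mm^3), `endocranial_surface` (mm^2),
#'   `neocortex_surface` (mm^2), `olfactory_bulb_volume` (mm^3),
#'   `petrosal_lobule_volume` (mm^3, NA allowed).
#' @return The validated data.frame, `locomotion` as a factor with
#'   `"arboreal"` as reference level.
#' @export
trait_table <- function(df) {
  missing_cols <- setdiff(TRAIT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("trait table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[TRAIT_COLUMNS]
  if (anyDuplicated(df$species)) {
    stop("duplicate species in trait table", call. = FALSE)
  }
  if (!all(df$status %in% c("extant", "extinct"))) {
    stop("status must be 'extant' or 'extinct'", call. = FALSE)
  }
  bad_loc <- setdiff(unique(as.character(df$locomotion)), LOCOMOTOR_LEVELS)
  if (length(bad_loc)) {
    stop("unknown locomotor categories: ", paste(bad_loc, collapse = ", "),
         "; expected one of ", paste(LOCOMOTOR_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  df$locomotion <- factor(as.character(df$locomotion),
                          levels = LOCOMOTOR_LEVELS)
  num_cols <- TRAIT_COLUMNS[-(1:3)]
  for (cl in num_cols) {
    v <- df[[cl]]
    if (any(!is.na(v) & v <= 0)) {
      stop("non-positive values in '", cl, "'", call. = FALSE)
    }
  }
  both <- function(a, b) !is.na(a) & !is.na(b)
  if (any(both(df$neocortex_surface, df$endocranial_surface) &
          df$neocortex_surface > df$endocranial_surface)) {
    warning("neocortex_surface exceeds endocranial_surface for some rows")
  }
  if (any(both(df$olfactory_bulb_volume, df$endocranial_volume) &
          df$olfactory_bulb_volume >= df$endocranial_volume)) {
    stop("olfactory_bulb_volume must be < endocranial_volume", call. = FALSE)
  }
  if (any(both(df$petrosal_lobule_volume, df$endocranial_volume) &
          df$petrosal_lobule_volume >= df$endocranial_volume)) {
    stop("petrosal_lobule_volume must be < endocranial_volume", call. = FALSE)
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#'
#' @param path CSV file with the columns documented in [trait_table()].
#' @return A validated trait table.
#' @export
read_trait_table <- function(path) {
  trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
write_trait_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
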