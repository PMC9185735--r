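#' Species parameter set for the ecoclimatic model
#'
#' Bundles the sixteen thresholds and rates that drive the weekly growth
#' indices and the four climatic stresses: the temperature response
#' (`dv0 < dv1 <= dv2 < dv3`, degrees C, applied to weekly mean
#' temperature), the soil-moisture response (`sm0 < sm1 <= sm2 < sm3`,
#' fractions of field capacity), and threshold/rate pairs for cold
#' (`ttcs`/`thcs`), heat (`tths`/`thhs`), dry (`smds`/`hds`) and wet
#' (`smws`/`hws`) stress. Stress rates are per (unit exceedance x week).
#'
#' The shipped parameter file for *Heterorhabditis indica* is available at
#' `system.file("extdata", "heterorhabditis_indica.params", package = "ecoclim")`.
#'
#' @param dv0,dv1,dv2,dv3 Temperature response: limiting low, lower optimum,
#'   upper optimum and limiting high temperature (degrees C).
#' @param sm0,sm1,sm2,sm3 Soil-moisture response: limiting low, lower
#'   optimum, upper optimum and limiting high soil moisture (fraction of
#'   field capacity; values above 1 are possible in waterlogged soil).
#' @param ttcs,thcs Cold stress threshold (degrees C, on weekly minimum
#'   temperature) and weekly accumulation rate.
#' @param tths,thhs Heat stress threshold (degrees C, on weekly mean
#'   temperature) and weekly accumulation rate.
#' @param smds,hds Dry stress threshold (soil-moisture fraction) and rate.
#' @param smws,hws Wet stress threshold (soil-moisture fraction) and rate.
#' @param species_name,notes Free-text labels carried through outputs.
#' @return An object of class `species_parameters` (a named list).
#' @seealso [load_species_parameters()], [validate_parameters()]
#' @export
#' @examples
#' p <- load_species_parameters(
#'   system.file("extdata", "heterorhabditis_indica.params", package = "ecoclim"))
#' p$dv0  # 18 degrees C
species_parameters <- function(dv0, dv1, dv2, dv3,
                               sm0, sm1, sm2, sm3,
                               ttcs, thcs, tths, thhs,
                               smds, hds, smws, hws,
                               species_name = "", notes = "") {
  p <- structure(
    list(dv0 = dv0, dv1 = dv1, dv2 = dv2, dv3 = dv3,
         sm0 = sm0, sm1 = sm1, sm2 = sm2, sm3 = sm3,
         ttcs = ttcs, thcs = thcs, tths = tths, thhs = thhs,
         smds = smds, hds = hds, smws = smws, hws = hws,
         species_name = as.character(species_name),
         notes = as.character(notes)),
    class = "species_parameters")
  num <- .param_numeric_fields
  bad <- num[!vapply(p[num], function(x) is.numeric(x) && length(x) == 1L &&
                       is.finite(x), logical(1))]
  if (length(bad))
    stop_validation("non-numeric or missing parameter value(s): %s",
                    paste(bad, collapse = ", "))
  viol <- validate_parameters(p)
  if (length(viol))
    stop_validation("invalid species parameters: %s",
                    paste(viol, collapse = "; "))
  p
}

.param_numeric_fields <- c("dv0", "dv1", "dv2", "dv3",
                           "sm0", "sm1", "sm2", "sm3",
                           "ttcs", "thcs", "tths", "thhs",
                           "smds", "hds", "smws", "hws")

#' Check a species parameter set against its internal orderings
#'
#' The orderings are: `dv0 < dv1 <= dv2 < dv3`; `sm0 < sm1 <= sm2 < sm3`;
#' the stress thresholds must sit outside the growth support
#' (`ttcs <= dv0`, `tths >= dv3`, `smds <= sm0`, `smws >= sm3`; equality is
#' legal and used by the shipped *H. indica* set); all four stress rates
#' must be strictly positive.
#'
#' @param p A list carrying the sixteen numeric fields of
#'   [species_parameters()] (it need not be a validated object).
#' @return A character vector of violation descriptions; empty when the
#'   parameter set is valid. Each entry names the violated relation and the
#'   offending values.
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  chk <- function(cond, fmt, ...) if (!isTRUE(cond)) v <<- c(v, sprintf(fmt, ...))
  chk(p$dv0 < p$dv1, "dv0 < dv1 violated (dv0=%g, dv1=%g)", p$dv0, p$dv1)
  chk(p$dv1 <= p$dv2, "dv1 <= dv2 violated (dv1=%g, dv2=%g)", p$dv1, p$dv2)
  chk(p$dv2 < p$dv3, "dv2 < dv3 violated (dv2=%g, dv3=%g)", p$dv2, p$dv3)
  chk(p$sm0 < p$sm1, "sm0 < sm1 violated (sm0=%g, sm1=%g)", p$sm0, p$sm1)
  chk(p$sm1 <= p$sm2, "sm1 <= sm2 violated (sm1=%g, sm2=%g)", p$sm1, p$sm2)
  chk(p$sm2 < p$sm3, "sm2 < sm3 violated (sm2=%g, sm3=%g)", p$sm2, p$sm3)
  chk(p$ttcs <= p$dv0, "ttcs <= dv0 violated (ttcs=%g, dv0=%g)", p$ttcs, p$dv0)
  chk(p$tths >= p$dv3, "tths >= dv3 violated (tths=%g, dv3=%g)", p$tths, p$dv3)
  chk(p$smds <= p$sm0, "smds <= sm0 violated (smds=%g, sm0=%g)", p$smds, p$sm0)
  chk(p$smws >= p$sm3, "smws >= sm3 violated (smws=%g, sm3=%g)", p$smws, p$sm3)
  for (r in c("thcs", "thhs", "hds", "hws"))
    chk(p[[r]] > 0, "rates > 0 violated (%s=%g)", r, p[[r]])
  v
}

#' Read a species parameter file
#'
#' The file format is flat `key = value` plain text, one parameter per
#' line, with `#` comments and blank lines ignored. All sixteen numeric
#' keys of [species_parameters()] are required; `species_name` and `notes`
#' are optional text.
#'
#' @param path Path to the parameter file.
#' @return A validated [species_parameters()] object.
#' @export
load_species_parameters <- function(path) {
  if (!file.exists(path)) stop_io("parameter file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) == 0L]
  if (length(bad))
    stop_validation("unparseable parameter line(s): %s",
                    paste(sQuote(bad), collapse = ", "))
  keys <- tolower(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  missing <- setdiff(.param_numeric_fields, keys)
  if (length(missing))
    stop_validation("missing parameter key(s): %s",
                    paste(missing, collapse = ", "))
  num <- suppressWarnings(as.numeric(vals[match(.param_numeric_fields, keys)]))
  if (anyNA(num))
    stop_validation("non-numeric value for key(s): %s",
                    paste(.param_numeric_fields[is.na(num)], collapse = ", "))
  args <- as.list(num)
  names(args) <- .param_numeric_fields
  args$species_name <- if ("species_name" %in% keys)
    vals[match("species_name", keys)] else ""
  args$notes <- if ("notes" %in% keys) vals[match("notes", keys)] else ""
  do.call(species_parameters, args)
}

#' Write a species parameter file
#'
#' Writes the flat `key = value` format read by
#' [load_species_parameters()]; the round trip reproduces all sixteen
#' numbers exactly (values are printed with full double precision).
#'
#' @param p A valid [species_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_parameters <- function(p, path) {
  viol <- validate_parameters(p)
  if (length(viol))
    stop_validation("refusing to write invalid parameters: %s",
                    paste(viol, collapse = "; "))
  num <- vapply(p[.param_numeric_fields], function(x)
    format(x, digits = 17, scientific = FALSE, trim = TRUE), character(1))
  lines <- c("# ecoclim species parameter file",
             paste(.param_numeric_fields, "=", num),
             paste("species_name =", p$species_name),
             paste("notes =", p$notes))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_io("cannot write %s: %s", path,
                                              conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @export
print.species_parameters <- function(x, ...) {
  cat("Species parameter set:",
      if (nzchar(x$species_name)) x$species_name else "(unnamed)", "\n")
  cat(sprintf("  temperature response (C):  DV0=%g  DV1=%g  DV2=%g  DV3=%g\n",
              x$dv0, x$dv1, x$dv2, x$dv3))
  cat(sprintf("  moisture response (frac):  SM0=%g  SM1=%g  SM2=%g  SM3=%g\n",
              x$sm0, x$sm1, x$sm2, x$sm3))
  cat(sprintf("  cold stress: TTCS=%g C, THCS=%g   heat stress: TTHS=%g C, THHS=%g\n",
              x$ttcs, x$thcs, x$tths, x$thhs))
  cat(sprintf("  dry stress:  SMDS=%g,  HDS=%g     wet stress:  SMWS=%g,  HWS=%g\n",
              x$smds, x$hds, x$smws, x$hws))
  invisible(x)
}
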