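#' Measurement cycle schedule of the TDL valve sequence
#'
#' The TDL cycles through eight gas streams: CO2-free air, three calibration
#' concentrations of identical isotopic composition, a certified tank, the
#' reference air, the leaf-chamber (sample) air for an extended period, and
#' the reference air again. The default schedule uses 20 s per phase except a
#' 600 s sample phase, for a total cycle of 740 s.
#'
#' @param phases Data frame with columns `site_id` and `duration_s`.
#' @param discard_head_s Seconds discarded at the head of every phase while
#'   the gas line flushes. Default 10.
#' @param block_s Averaging block length in seconds. Default 10.
#' @return A list with class `"cycle_schedule"`: `phases`, `total_duration_s`,
#'   `discard_head_s`, `block_s`.
#' @export
#' @examples
#' sch <- cycle_schedule()
#' sch$total_duration_s  # 740
cycle_schedule <- function(phases = NULL, discard_head_s = 10, block_s = 10) {
  if (is.null(phases)) {
    phases <- data.frame(
      site_id = c("zero_air", "cal1", "cal2", "cal3", "tank",
                  "reference", "sample", "reference"),
      duration_s = c(20, 20, 20, 20, 20, 20, 600, 20),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(phases),
            all(c("site_id", "duration_s") %in% names(phases)),
            all(phases$duration_s > 0))
  if (any(phases$duration_s <= discard_head_s))
    stop("every phase must be longer than discard_head_s (",
         discard_head_s, " s); offending phase(s): ",
         paste(phases$site_id[phases$duration_s <= discard_head_s],
               collapse = ", "))
  out <- list(phases = phases,
              total_duration_s = sum(phases$duration_s),
              discard_head_s = discard_head_s,
              block_s = block_s)
  class(out) <- "cycle_schedule"
  out
}

#' Column dialects for gas-exchange log files
#'
#' A dialect maps native column names of a gas-exchange system's log file to
#' the canonical fields used by this package, together with multiplicative
#' unit conversions into the canonical units (times in s, fluxes in
#' umol m-2 s-1, E in mol m-2 s-1, conductances in mol m-2 s-1, CO2 in
#' umol mol-1, temperature in degrees C, flow in umol s-1).
#'
#' Two dialects ship with the package: `"c4leak"` (the canonical column names,
#' written by the simulator) and `"li6400"` (typical LI-6400XT export names,
#' with Trmmol converted from mmol to mol and Area from cm2 to m2).
#'
#' @param name Dialect name, or a list with elements `columns` (named
#'   character vector canonical -> native) and optional `scale` (named numeric
#'   vector of multipliers on canonical fields).
#' @return A list with elements `columns` and `scale`.
#' @export
gasex_dialect <- function(name = "c4leak") {
  if (is.list(name)) {
    stopifnot(!is.null(name$columns))
    return(list(columns = unlist(name$columns),
                scale = if (is.null(name$scale)) numeric() else unlist(name$scale)))
  }
  switch(name,
    c4leak = list(
      columns = c(time_s = "time_s", A = "A", E = "E", gs = "gs",
                  gact = "gact", Ca = "Ca", Ci = "Ci", Cs = "Cs",
                  Tleaf = "Tleaf", flow = "flow", Rd = "Rd"),
      scale = numeric()),
    li6400 = list(
      columns = c(time_s = "FTime", A = "Photo", E = "Trmmol", gs = "Cond",
                  Ca = "CO2S", Ci = "Ci", Tleaf = "Tleaf", flow = "Flow"),
      scale = c(E = 1e-3)),
    stop("unknown gas-exchange dialect '", name,
         "'; supply an explicit column map"))
}

#' Read a gas-exchange log into canonical records
#'
#' Reads a delimited text log (comma or tab separated, header row required)
#' and returns one record per logged timepoint in canonical units. Optional
#' fields absent from the file are derived: total conductance to CO2 (`gact`)
#' as the series combination of boundary-layer and stomatal conductances
#' using the 1.37 and 1.6 diffusivity ratios, and leaf-surface CO2 (`Cs`)
#' from the boundary-layer drawdown.
#'
#' @param path File path.
#' @param dialect Dialect name or explicit map, see [gasex_dialect()].
#' @param gbw Boundary-layer conductance to water vapour (mol m-2 s-1) used
#'   when `gact`/`Cs` must be derived. Default 3.
#' @param rd Dark respiration (umol m-2 s-1) used when the log has no `Rd`
#'   column.
#' @return A data frame of records ordered by time with columns `time_s`,
#'   `A`, `E`, `gs`, `gact`, `Ca`, `Ci`, `Cs`, `Tleaf`, `flow`, `Rd` and
#'   attribute `derived` naming any derived fields.
#' @export
read_gas_exchange_log <- function(path, dialect = "c4leak", gbw = 3,
                                  rd = NULL) {
  d <- gasex_dialect(dialect)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  mandatory <- c("time_s", "A", "E", "gs", "Ca", "Ci", "Tleaf", "flow")
  missing_map <- setdiff(mandatory, names(d$columns))
  if (length(missing_map))
    stop("dialect does not map mandatory field(s): ",
         paste(missing_map, collapse = ", "))
  native_needed <- d$columns[mandatory]
  absent <- setdiff(native_needed, names(raw))
  if (length(absent))
    stop("gas-exchange log lacks mandatory column(s): ",
         paste(absent, collapse = ", "))

  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(d$columns)) {
    native <- d$columns[[canon]]
    if (native %in% names(raw)) rec[[canon]] <- as.numeric(raw[[native]])
  }
  for (canon in names(d$scale))
    if (canon %in% names(rec)) rec[[canon]] <- rec[[canon]] * d$scale[[canon]]

  dt <- diff(rec$time_s)
  if (any(dt <= 0))
    stop("time_s is not strictly increasing at row(s): ",
         paste(utils::head(which(dt <= 0) + 1L, 10L), collapse = ", "))

  derived <- character()
  if (is.null(rec$gact)) {
    gbc <- gbw / 1.37
    gsc <- rec$gs / 1.6
    rec$gact <- 1 / (1 / gbc + 1 / gsc)
    derived <- c(derived, "gact")
  }
  if (is.null(rec$Cs)) {
    rec$Cs <- rec$Ca - rec$A / (gbw / 1.37)
    derived <- c(derived, "Cs")
  }
  if (is.null(rec$Rd)) {
    if (is.null(rd))
      stop("log has no Rd column and no 'rd' fallback was supplied")
    rec$Rd <- rd
    derived <- c(derived, "Rd")
  }
  rec <- rec[c("time_s", "A", "E", "gs", "gact", "Ca", "Ci", "Cs",
               "Tleaf", "flow", "Rd")]
  attr(rec, "derived") <- derived
  rec
}

#' Segment a raw TDL stream into calibration cycles of 10 s block means
#'
#' Splits a 10 Hz isotopologue stream into measurement cycles according to
#' the valve schedule, discards the head of every phase while the line
#' flushes, and averages the remainder in consecutive blocks. With the
#' default schedule each 20 s phase yields one block and the 600 s sample
#' phase yields 59 blocks. Block timestamps are block centres.
#'
#' Every raw sample is either averaged into exactly one block or explicitly
#' discarded (head of phase); nothing is silently lost.
#'
#' @param samples Data frame with columns `time_s`, `site_id`, `c12`, `c13`;
#'   `time_s` strictly increasing at a nominal 10 Hz.
#' @param schedule A [cycle_schedule()].
#' @param cycle_start_s Run time at which the first cycle starts. Default:
#'   the first sample time.
#' @return A list with class `"calibration_cycles"`; each element is a list
#'   with `cycle_index`, `blocks` (data frame: `site_id`, `phase`,
#'   `time_s`, `c12`, `c13`, `n_samples`, `low_coverage`),
#'   `reference_before` and `reference_after` (one-row block data frames
#'   bracketing the sample phase).
#' @export
segment_cycles <- function(samples, schedule = cycle_schedule(),
                           cycle_start_s = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("time_s", "site_id", "c12", "c13") %in% names(samples)))
  if (is.unsorted(samples$time_s, strictly = TRUE))
    stop("TDL sample times must be strictly increasing")
  if (is.null(cycle_start_s)) cycle_start_s <- samples$time_s[1]

  ph <- schedule$phases
  offs <- cumsum(c(0, ph$duration_s))  # phase offsets within a cycle
  total <- schedule$total_duration_s
  blk <- schedule$block_s
  dt <- stats::median(diff(samples$time_s))
  nominal_per_block <- round(blk / dt)

  tsrel <- samples$time_s - cycle_start_s
  cyc <- floor(tsrel / total)
  cycles <- list()
  sample_phase <- which(ph$site_id == "sample")
  ref_phases <- which(ph$site_id == "reference")

  for (k in sort(unique(cyc))) {
    if (k < 0) next
    sel <- cyc == k
    t_in <- tsrel[sel] - k * total
    sub <- samples[sel, , drop = FALSE]
    phase_idx <- findInterval(t_in, offs, rightmost.closed = FALSE)
    phase_idx[phase_idx > nrow(ph)] <- nrow(ph)  # guard exact total boundary
    rows <- list()
    for (p in seq_len(nrow(ph))) {
      psel <- phase_idx == p
      if (!any(psel)) next
      seen <- unique(sub$site_id[psel])
      if (!identical(seen, ph$site_id[p]))
        stop("site sequence mismatch in cycle ", k, ", phase ", p,
             ": expected '", ph$site_id[p], "', saw '",
             paste(seen, collapse = "','"), "'")
      t_ph <- t_in[psel] - offs[p]
      keep <- t_ph >= schedule$discard_head_s
      if (!any(keep)) next
      bi <- floor((t_ph[keep] - schedule$discard_head_s) / blk)
      n_blocks <- floor((ph$duration_s[p] - schedule$discard_head_s) / blk)
      bi[bi >= n_blocks] <- n_blocks - 1L
      d <- sub[psel, , drop = FALSE][keep, , drop = FALSE]
      b_ids <- sort(unique(bi))
      agg <- data.frame(
        site_id = ph$site_id[p], phase = p,
        time_s = cycle_start_s + k * total + offs[p] +
          schedule$discard_head_s + b_ids * blk + blk / 2,
        c12 = vapply(b_ids, function(b) mean(d$c12[bi == b]), 0),
        c13 = vapply(b_ids, function(b) mean(d$c13[bi == b]), 0),
        n_samples = vapply(b_ids, function(b) sum(bi == b), 0L),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- agg
    }
    if (!length(rows)) next
    blocks <- do.call(rbind, rows)
    blocks$low_coverage <- blocks$n_samples < nominal_per_block / 2
    ref_b <- ref_a <- NULL
    if (length(sample_phase)) {
      before <- ref_phases[ref_phases < sample_phase]
      after <- ref_phases[ref_phases > sample_phase]
      if (length(before))
        ref_b <- blocks[blocks$phase == max(before), , drop = FALSE]
      if (length(after))
        ref_a <- blocks[blocks$phase == min(after), , drop = FALSE]
    }
    cycles[[length(cycles) + 1L]] <-
      list(cycle_index = k, blocks = blocks,
           reference_before = ref_b, reference_after = ref_a)
  }
  class(cycles) <- "calibration_cycles"
  cycles
}

#' Write / read a leakiness results table
#'
#' Writes one row per timepoint with the discrimination quantities, the
#' bundle-sheath model state and the leakiness estimate. A leading comment
#' line documents the units. `read_leakiness_table()` reads the file back.
#'
#' @param series Data frame as produced by [run_analysis()] (`$series`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_leakiness_table <- function(series, path) {
  cols <- c("time_s", "A", "gs", "Ci", "xi", "Delta_obs", "error",
            "error_pct", "included", "phi", "Cbs", "Jt", "Vp", "Vc", "Vo")
  out <- as.data.frame(series)[, intersect(cols, names(series)), drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste0(
    "# units: time_s s; A,Jt,Vp,Vc,Vo umol m-2 s-1; gs mol m-2 s-1; ",
    "Ci,Cbs umol mol-1; xi,phi unitless; Delta_obs,error permil; ",
    "error_pct percent"), con)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_leakiness_table
#' @export
read_leakiness_table <- function(path) {
  out <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if ("included" %in% names(out)) out$included <- as.logical(out$included)
  out
}
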