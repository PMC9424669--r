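# Raw record tables -> analysis-ready inputs: independent records,
# solar-time angles, and daily detection histories collapsed to binomial
# counts with effort.

#' Filter temporally independent records
#'
#' Within each (species, site) stream, records are walked in time order and
#' a record is retained only if it falls strictly more than
#' \code{gap_minutes} after the previously *retained* record of that stream
#' (sequential chain rule: every retained record resets the clock).  The
#' first record of a stream is always retained.  The default one-hour gap is
#' the camera-trap convention for independent detections.
#'
#' @param records data.frame with columns species, site_id, timestamp.
#' @param gap_minutes minimum separation in minutes (> means strictly more).
#' @return the retained rows, sorted by species, site and time.
#' @examples
#' r <- data.frame(species = "a", site_id = "s1",
#'   timestamp = as.POSIXct("2017-08-01 10:00", tz = "UTC") +
#'     c(0, 30, 90) * 60)
#' nrow(filterIndependent(r))  # 2: 10:00 and 11:30 survive the > 1 h rule
#' @export
filterIndependent <- function(records, gap_minutes = 60) {
  if (gap_minutes < 0) stop("gap_minutes must be non-negative")
  stopifnot(all(c("species", "site_id", "timestamp") %in% names(records)))
  if (nrow(records) == 0) return(records)
  ord <- order(records$species, records$site_id, records$timestamp)
  rec <- records[ord, ]
  grp <- paste(rec$species, rec$site_id, sep = "\r")
  keep <- logical(nrow(rec))
  t_num <- as.numeric(rec$timestamp)
  for (g in split(seq_len(nrow(rec)), grp)) {
    last <- -Inf
    for (i in g) {
      if (t_num[i] - last > gap_minutes * 60) {
        keep[i] <- TRUE
        last <- t_num[i]
      }
    }
  }
  out <- rec[keep, ]
  rownames(out) <- NULL
  out
}

# Equation of time, minutes (Spencer's Fourier expansion); doy in 1..366
.equation_of_time <- function(doy) {
  B <- 2 * pi * (doy - 1) / 365
  229.18 * (0.000075 + 0.001868 * cos(B) - 0.032077 * sin(B) -
              0.014615 * cos(2 * B) - 0.040849 * sin(2 * B))
}

#' Convert clock time to a solar-time angle
#'
#' Computes local apparent solar time (clock time corrected by the site's
#' longitude offset from the timezone meridian plus the equation of time)
#' and maps it to an angle in [0, 2*pi) with solar noon at pi and solar
#' midnight at 0.
#'
#' @param timestamp POSIXct; its displayed clock reading is taken as local
#'   civil time.
#' @param longitude degrees east in [-180, 180].
#' @param tz_offset civil timezone offset from UTC in hours (e.g. 2 for
#'   South African Standard Time).
#' @return numeric vector of angles in radians, [0, 2*pi).
#' @export
toSolarTime <- function(timestamp, longitude, tz_offset = 2) {
  if (any(longitude < -180 | longitude > 180))
    stop("longitude must be within [-180, 180] degrees")
  lt <- as.POSIXlt(timestamp)
  doy <- lt$yday + 1
  clock_min <- lt$hour * 60 + lt$min + lt$sec / 60
  corr <- 4 * (longitude - 15 * tz_offset) + .equation_of_time(doy)
  .wrap_angle((clock_min + corr) / 1440 * 2 * pi)
}

#' Annotate a record table with solar time and independence
#'
#' Convenience wrapper: adds a \code{solar_time} column (radians) using each
#' record's site longitude, and an \code{independent} flag from
#' [filterIndependent()].
#'
#' @param records record data.frame (species, site_id, timestamp).
#' @param sites site table with site_id and longitude.
#' @param gap_minutes independence gap, minutes.
#' @param tz_offset civil timezone offset, hours.
#' @return records with solar_time and independent columns.
#' @export
annotateRecords <- function(records, sites, gap_minutes = 60, tz_offset = 2) {
  lon <- sites$longitude[match(records$site_id, sites$site_id)]
  if (anyNA(lon)) stop("records reference sites absent from the site table")
  records$solar_time <- toSolarTime(records$timestamp, lon, tz_offset)
  kept <- filterIndependent(records, gap_minutes)
  key <- function(d) paste(d$species, d$site_id, as.numeric(d$timestamp))
  records$independent <- key(records) %in% key(kept)
  records
}

#' Collapse records to daily detection histories with effort
#'
#' Builds the species x site matrix of detection-day counts: y_ij = number
#' of distinct deployment days with at least one record of species i at
#' site j; effort k_j = active trap-days of site j.  Species listed in
#' \code{assemblage} but never recorded are kept as all-zero rows.
#'
#' @param records record data.frame (species, site_id, timestamp).
#' @param sites site table (one area) with deploy_start, deploy_end, effort.
#' @param assemblage optional character vector of species to tabulate;
#'   defaults to the species observed in \code{records}.
#' @return a \linkS4class{DetectionData}.
#' @export
buildDetectionData <- function(records, sites, assemblage = NULL) {
  j <- match(records$site_id, sites$site_id)
  if (anyNA(j)) {
    bad <- unique(records$site_id[is.na(j)])
    stop("records reference unknown site(s): ", paste(bad, collapse = ", "))
  }
  day <- as.Date(records$timestamp)
  out_win <- day < sites$deploy_start[j] | day > sites$deploy_end[j]
  if (any(out_win)) {
    i <- which(out_win)[1]
    stop(sprintf("record outside deployment window: site %s at %s",
                 records$site_id[i], format(records$timestamp[i])))
  }
  sp <- if (is.null(assemblage)) sort(unique(records$species)) else assemblage
  unknown <- setdiff(records$species, sp)
  if (length(unknown))
    stop("records for species not in the assemblage: ",
         paste(unknown, collapse = ", "))
  y <- matrix(0L, length(sp), nrow(sites),
              dimnames = list(sp, sites$site_id))
  if (nrow(records)) {
    dd <- unique(data.frame(species = records$species,
                            site_id = records$site_id, day = day))
    tab <- table(factor(dd$species, levels = sp),
                 factor(dd$site_id, levels = sites$site_id))
    y[] <- as.integer(tab)
  }
  .makeDetectionData(y, sites)
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read and write pipeline tables as CSV
#'
#' Plain-CSV persistence for the pipeline's tables.  Record tables carry
#' ISO-8601 timestamps (UTC); site tables carry ISO dates.  Detection data
#' are written as two files: \code{<stem>_counts.csv} (species x site
#' detection-day counts) and \code{<stem>_sites.csv} (site covariates and
#' effort).
#'
#' @param records,sites,x objects to write.
#' @param path,stem file path / file stem.
#' @return the read functions return the corresponding object.
#' @name coocc-io
#' @export
writeRecordTable <- function(records, path) {
  out <- records
  out$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname coocc-io
#' @export
readRecordTable <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE)
  r$timestamp <- as.POSIXct(r$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  r
}

#' @rdname coocc-io
#' @export
writeSiteTable <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname coocc-io
#' @export
readSiteTable <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  for (v in c("deploy_start", "deploy_end"))
    if (v %in% names(s)) s[[v]] <- as.Date(s[[v]])
  s
}

#' @rdname coocc-io
#' @export
writeDetectionData <- function(x, stem) {
  y <- detections(x)
  write.csv(data.frame(species = rownames(y), y, check.names = FALSE),
            paste0(stem, "_counts.csv"), row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  write.csv(cd, paste0(stem, "_sites.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname coocc-io
#' @export
readDetectionData <- function(stem) {
  cnt <- read.csv(paste0(stem, "_counts.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  sites <- readSiteTable(paste0(stem, "_sites.csv"))
  y <- as.matrix(cnt[, -1, drop = FALSE])
  storage.mode(y) <- "integer"
  rownames(y) <- cnt$species
  .makeDetectionData(y, sites)
}
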