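# Named seed substreams: one user-facing seed per dataset/run, expanded into
# independent per-stage seeds so any stage can be rerun in isolation.
.substream_offsets <- c(
  sites = 1L, community = 2L, occupancy = 3L, records = 4L,
  jsdm = 5L, drivers = 6L, report = 7L
)

#' Derive a named per-stage seed from a master seed
#'
#' Each pipeline stage consumes its own deterministic substream of the master
#' seed, so rerunning one stage reproduces its output without replaying the
#' stages before it.
#'
#' @param seed integer master seed.
#' @param stream one of "sites", "community", "occupancy", "records",
#'   "jsdm", "drivers", "report".
#' @param index optional extra index (e.g. per-area or per-chain).
#' @return an integer seed below 2^31.
#' @export
substreamSeed <- function(seed, stream = names(.substream_offsets),
                          index = 0L) {
  stream <- match.arg(stream)
  base <- (as.numeric(seed) %% 900000011) + 1
  off <- as.numeric(.substream_offsets[[stream]])
  # multiplicative hash keeps distinct (seed, stream, index) triples apart
  as.integer((base * 2654435761 + off * 40503 + as.numeric(index) * 69621) %%
               2147483647)
}

.assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

# standardize to mean 0 / sd 1; explicit, never silent (see restandardize())
.standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant covariate", call. = FALSE)
  (x - mean(x)) / s
}

#' Restandardize site covariates within an area
#'
#' Standardization (mean 0, SD 1 per area) is part of the model definition;
#' after any subsetting of sites it must be re-declared explicitly.  This
#' helper recomputes the standardization of TREE, TRAIL_W and VEG_D within
#' each area of a site table.
#'
#' @param sites a site data.frame with columns area, TREE, TRAIL_W, VEG_D.
#' @return the site table with covariates re-standardized per area.
#' @export
restandardize <- function(sites) {
  for (a in unique(sites$area)) {
    i <- sites$area == a
    if (sum(i) < 2) stop("need at least 2 sites per area to standardize")
    for (v in c("TREE", "TRAIL_W", "VEG_D")) sites[[v]][i] <- .standardize(sites[[v]][i])
  }
  sites
}

.wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  y[y < 0] <- y[y < 0] + 2 * pi
  y
}

.pairs_of <- function(sp) {
  if (length(sp) < 2) return(data.frame(species_a = character(), species_b = character()))
  idx <- utils::combn(seq_along(sp), 2)
  data.frame(species_a = sp[idx[1, ]], species_b = sp[idx[2, ]],
             stringsAsFactors = FALSE)
}
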