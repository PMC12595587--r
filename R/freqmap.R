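#' @title Global frequency heatmaps
#' @description
#' A variant specifier (an allele, an amino-acid motif, or a multi-locus
#' haplotype) plus a population frequency table yields one point value per
#' population; the points are interpolated onto a regular
#' latitude-longitude grid by inverse-distance weighting over great-circle
#' distances, masked to land within a cutoff distance of any observation,
#' and rendered as a colour (blue -> red) or greyscale (white -> black)
#' world map with each contributing population drawn as a white dot.
#' @name freqmap
NULL

.hk_env <- new.env(parent = emptyenv())

HK_LOW_FREQ <- 1e-4

hk_condition <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "hk_error")))
}

#' Compute per-population point values for a variant
#'
#' @param spec variant specifier: an allele name (`"B*27:02"`), a motif
#'   (`"DRB1*25R~38V~48R~127I"`) or a haplotype (`"A*26:01~C*03:03"`).
#' @param kind one of `"allele"`, `"motif"`, `"haplotype"`.
#' @param freq an `hk_freq_table` (allele/motif) or `hk_hap_table`
#'   (haplotype).
#' @param aln protein `hla_alignment` for the motif's locus (motif kind
#'   only).
#' @param filter_migrant drop populations flagged migrant/admixed.
#' @param generate_low_freq allow maps whose point values are all below
#'   `1e-4`; otherwise such variants raise a condition of class
#'   `hk_low_frequency`.
#' @return data frame `population`, `lat`, `lon`, `value` with attributes
#'   `matched_alleles` and `dropped_migrant`.  Motif values are the sum of
#'   the population's frequencies over all alleles carrying the motif;
#'   haplotype values sum the rows whose requested loci, truncated to the
#'   spec's field depth, equal the spec.  A variant observed in no
#'   population raises a condition of class `hk_not_observed`.
#' @export
select_variant <- function(spec, kind = c("allele", "motif", "haplotype"),
                           freq, aln = NULL, filter_migrant = FALSE,
                           generate_low_freq = FALSE) {
  kind <- match.arg(kind)
  dropped <- character(0)
  if (kind %in% c("allele", "motif")) {
    stopifnot(inherits(freq, "hk_freq_table"))
    if (filter_migrant) {
      dropped <- unique(freq$popname[freq$migrant])
      freq <- freq[!freq$migrant, , drop = FALSE]
    }
  }

  if (kind == "allele") {
    allele <- parse_hla_allele(spec)
    sub <- freq[freq$locus == allele$locus, , drop = FALSE]
    if (nrow(sub) == 0L) {
      hk_condition("hk_not_observed",
                   paste0("no populations typed at locus ", allele$locus))
    }
    pops <- unique(sub[, c("popname", "latit", "longit")])
    hitrows <- sub[sub$allele == format(allele), , drop = FALSE]
    if (nrow(hitrows) == 0L) {
      hk_condition("hk_not_observed",
                   paste0("allele ", spec, " observed in no population"))
    }
    vals <- tapply(hitrows$frequency, hitrows$popname, sum)
    out <- data.frame(population = pops$popname, lat = pops$latit,
                      lon = pops$longit,
                      value = unname(ifelse(is.na(vals[pops$popname]), 0,
                                            vals[pops$popname])),
                      stringsAsFactors = FALSE)
    matched <- format(allele)
  } else if (kind == "motif") {
    motif <- if (is.character(spec)) parse_motif(spec) else spec
    if (is.null(aln)) {
      stop("motif maps need the locus protein alignment (aln)", call. = FALSE)
    }
    if (aln$locus != motif$locus) {
      stop("alignment locus ", aln$locus, " does not match motif locus ",
           motif$locus, call. = FALSE)
    }
    full <- motif_match(motif, aln, truncate_to = NA)
    sub <- freq[freq$locus == motif$locus, , drop = FALSE]
    if (nrow(sub) == 0L) {
      hk_condition("hk_not_observed",
                   paste0("no populations typed at locus ", motif$locus))
    }
    # a table allele matches if any full matching allele truncates to it
    tab_alleles <- unique(sub$allele)
    matched <- tab_alleles[vapply(tab_alleles, function(a) {
      k <- allele_field_count(a)
      a %in% unique(truncate_names(full, k))
    }, logical(1))]
    if (length(matched) == 0L) {
      hk_condition("hk_not_observed",
                   paste0("motif ", render_motif(motif),
                          " matches no allele in the frequency table"))
    }
    pops <- unique(sub[, c("popname", "latit", "longit")])
    hitrows <- sub[sub$allele %in% matched, , drop = FALSE]
    vals <- tapply(hitrows$frequency, hitrows$popname, sum)
    out <- data.frame(population = pops$popname, lat = pops$latit,
                      lon = pops$longit,
                      value = unname(ifelse(is.na(vals[pops$popname]), 0,
                                            vals[pops$popname])),
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(freq, "hk_hap_table"))
    comps <- lapply(strsplit(spec, "~", fixed = TRUE)[[1]], parse_hla_allele)
    req_loci <- vapply(comps, `[[`, character(1), "locus")
    req_depth <- vapply(comps, function(a) length(a$fields), integer(1))
    req_names <- vapply(comps, format, character(1))
    pops <- unique(freq[, c("population", "latit", "longit")])
    keep <- logical(nrow(pops))
    value <- numeric(nrow(pops))
    for (i in seq_len(nrow(pops))) {
      rows <- freq[freq$population == pops$population[i], , drop = FALSE]
      parts <- strsplit(rows$haplotype[1L], "~", fixed = TRUE)[[1]]
      part_alleles <- lapply(parts, parse_hla_allele)
      loci <- vapply(part_alleles, `[[`, character(1), "locus")
      at <- match(req_loci, loci)
      if (anyNA(at)) next                       # population lacks a locus
      depths <- vapply(part_alleles[at], function(a) length(a$fields),
                       integer(1))
      if (any(depths < req_depth)) next         # recorded depth too shallow
      keep[i] <- TRUE
      for (j in seq_len(nrow(rows))) {
        pj <- strsplit(rows$haplotype[j], "~", fixed = TRUE)[[1]]
        got <- vapply(seq_along(req_loci), function(k) {
          format(truncate_allele(parse_hla_allele(pj[at[k]]),
                                 req_depth[k])) == req_names[k]
        }, logical(1))
        if (all(got)) value[i] <- value[i] + rows$frequency[j]
      }
    }
    if (!any(keep)) {
      hk_condition("hk_not_observed",
                   paste0("no population records all loci of ", spec,
                          " at the requested resolution"))
    }
    out <- data.frame(population = pops$population[keep],
                      lat = pops$latit[keep], lon = pops$longit[keep],
                      value = value[keep], stringsAsFactors = FALSE)
    matched <- spec
  }

  if (nrow(out) == 0L) {
    hk_condition("hk_not_observed",
                 "no populations left after filtering")
  }
  if (all(out$value < HK_LOW_FREQ) && !generate_low_freq) {
    hk_condition("hk_low_frequency",
                 paste0("all point values for ", if (is.character(spec)) spec
                        else render_motif(spec), " are below ", HK_LOW_FREQ,
                        "; set generate_low_freq = TRUE to map anyway"))
  }
  attr(out, "matched_alleles") <- matched
  attr(out, "dropped_migrant") <- dropped
  out
}

## ---- land mask --------------------------------------------------------

#' Load the synthetic coastline polygons
#'
#' A coarse, hand-digitised set of continental outlines (synthetic: drawn
#' for masking at 1-2 degree grid resolution, not a survey-accurate
#' coastline) shipped as `inst/extdata/synthetic_coastlines.csv` with
#' columns `polygon`, `lon`, `lat`.
#' @return data frame of polygon vertices.
#' @export
hk_coastlines <- function() {
  utils::read.csv(system.file("extdata", "synthetic_coastlines.csv",
                              package = "hlakit"),
                  stringsAsFactors = FALSE)
}

# even-odd ray casting, vectorized over points
hk_point_in_polygon <- function(px, py, vx, vy) {
  inside <- rep(FALSE, length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Land mask at a given grid resolution
#' @param resolution cell size in degrees.
#' @param coastlines polygon vertex table, defaulting to the packaged
#'   synthetic coastlines.
#' @return logical matrix (lat rows south to north, lon columns west to
#'   east): `TRUE` for land cells; cached per resolution.
#' @export
hk_land_mask <- function(resolution = 1, coastlines = NULL) {
  key <- paste0("land_", resolution, if (is.null(coastlines)) "_default")
  if (is.null(coastlines)) {
    cached <- .hk_env[[key]]
    if (!is.null(cached)) return(cached)
    coastlines <- hk_coastlines()
  }
  lat_c <- seq(-90 + resolution / 2, 90 - resolution / 2, by = resolution)
  lon_c <- seq(-180 + resolution / 2, 180 - resolution / 2, by = resolution)
  px <- rep(lon_c, each = length(lat_c))
  py <- rep(lat_c, times = length(lon_c))
  land <- rep(FALSE, length(px))
  # even-odd across polygons: a polygon inside another (an enclosed sea)
  # carves a hole
  for (id in unique(coastlines$polygon)) {
    v <- coastlines[coastlines$polygon == id, ]
    land <- xor(land, hk_point_in_polygon(px, py, v$lon, v$lat))
  }
  m <- matrix(land, nrow = length(lat_c), ncol = length(lon_c))
  dimnames(m) <- list(lat_c, lon_c)
  if (startsWith(key, "land_") && endsWith(key, "_default")) .hk_env[[key]] <- m
  m
}

## ---- gridding ---------------------------------------------------------

#' Interpolate population point values onto a global grid
#'
#' Inverse-distance weighting (power `power`) over great-circle (haversine)
#' distances.  Cells farther than `cutoff_km` from every observation are
#' masked, as are sea cells; the cell containing an observation is always
#' unmasked and carries the observation's value exactly (nearest point wins
#' if a cell holds several).  IDW output never overshoots the range of the
#' point values.
#'
#' @param points data frame with `lat`, `lon`, `value` (and optionally
#'   `population`), as returned by [select_variant()].
#' @param resolution grid cell size in degrees.
#' @param power IDW power.
#' @param cutoff_km distance mask cutoff in kilometres.
#' @param scale_mode `"data_max"` scales the colour range to the maximum
#'   point value; `"unit"` fixes it at 1.0 so maps of complementary
#'   variants share one scale.
#' @param land logical land-mask matrix, defaulting to
#'   `hk_land_mask(resolution)`.
#' @return An object of class `hk_heatgrid`: list with `lat`, `lon` (cell
#'   centers), `values` (matrix, `NA` where masked), `mask`, `vmax`,
#'   `scale_mode`, `points`, `resolution` and the IDW parameters.
#' @export
grid_frequencies <- function(points, resolution = 1, power = 2,
                             cutoff_km = 2000,
                             scale_mode = c("data_max", "unit"),
                             land = NULL) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(is.data.frame(points), all(c("lat", "lon", "value") %in%
                                         names(points)))
  if (nrow(points) == 0L) stop("no support points to grid", call. = FALSE)
  if (is.null(land)) land <- hk_land_mask(resolution)
  lat_c <- as.numeric(rownames(land))
  lon_c <- as.numeric(colnames(land))
  ncell <- length(lat_c) * length(lon_c)
  cell_lon <- rep(lon_c, each = length(lat_c))
  cell_lat <- rep(lat_c, times = length(lon_c))

  num <- numeric(ncell)
  den <- numeric(ncell)
  mind <- rep(Inf, ncell)
  for (i in seq_len(nrow(points))) {
    d <- geosphere::distHaversine(cbind(cell_lon, cell_lat),
                                  c(points$lon[i], points$lat[i])) / 1000
    mind <- pmin(mind, d)
    w <- 1 / pmax(d, 1e-9)^power
    num <- num + w * points$value[i]
    den <- den + w
  }
  vals <- num / den

  masked <- mind > cutoff_km | !as.vector(land)

  # cells containing observations: exact value of the nearest point, unmasked
  ci <- pmin(pmax(floor((points$lat + 90) / resolution) + 1L, 1L),
             length(lat_c))
  cj <- pmin(pmax(floor((points$lon + 180) / resolution) + 1L, 1L),
             length(lon_c))
  cell_of <- (cj - 1L) * length(lat_c) + ci
  for (cell in unique(cell_of)) {
    here <- which(cell_of == cell)
    if (length(here) > 1L) {
      d <- geosphere::distHaversine(
        cbind(points$lon[here], points$lat[here]),
        c(cell_lon[cell], cell_lat[cell]))
      here <- here[which.min(d)]
    }
    vals[cell] <- points$value[here]
    masked[cell] <- FALSE
  }
  vals[masked] <- NA_real_

  vmax <- if (scale_mode == "unit") 1.0 else max(points$value)
  structure(list(lat = lat_c, lon = lon_c,
                 values = matrix(vals, nrow = length(lat_c)),
                 mask = matrix(masked, nrow = length(lat_c)),
                 vmax = vmax, scale_mode = scale_mode, points = points,
                 resolution = resolution, power = power,
                 cutoff_km = cutoff_km),
            class = "hk_heatgrid")
}

#' @export
print.hk_heatgrid <- function(x, ...) {
  cat(sprintf("<hk_heatgrid> %gdeg grid, %d support points, vmax %.4g (%s), %d unmasked cells\n",
              x$resolution, nrow(x$points), x$vmax, x$scale_mode,
              sum(!x$mask)))
  invisible(x)
}

## ---- rendering --------------------------------------------------------

#' Render a heat grid to an image file
#'
#' @param grid an `hk_heatgrid`.
#' @param out_path output path; the extension selects the device (`.png`
#'   raster, `.svg` or `.pdf` vector).
#' @param color_mode `"color"` (blue lowest to red highest) or
#'   `"greyscale"` (white lowest to black highest).
#' @param title optional map title.
#' @param width,height device size in pixels (png) or inches (svg/pdf).
#' @return `out_path`, invisibly.
#' @export
render_map <- function(grid, out_path, color_mode = c("color", "greyscale"),
                       title = NULL, width = NULL, height = NULL) {
  color_mode <- match.arg(color_mode)
  stopifnot(inherits(grid, "hk_heatgrid"))
  ext <- tolower(tools::file_ext(out_path))
  if (!dir.exists(dirname(out_path))) {
    stop("cannot write map: directory '", dirname(out_path),
         "' does not exist", call. = FALSE)
  }
  if (ext == "png") {
    grDevices::png(out_path, width = width %||% 1200,
                   height = height %||% 700, type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(out_path, width = width %||% 12, height = height %||% 7)
  } else if (ext == "pdf") {
    grDevices::pdf(out_path, width = width %||% 12, height = height %||% 7)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  on.exit(grDevices::dev.off(), add = TRUE)

  pal <- if (color_mode == "color") {
    grDevices::colorRampPalette(
      c("#0000b4", "#00a0ff", "#00e08c", "#ffff00", "#ff8000", "#d40000"))(64)
  } else {
    grDevices::colorRampPalette(c("#ffffff", "#000000"))(64)
  }

  graphics::layout(matrix(1:2, nrow = 2), heights = c(6, 1.3))
  graphics::par(mar = c(1.5, 2.5, if (is.null(title)) 1 else 2.5, 1))
  vmax <- max(grid$vmax, 1e-12)
  graphics::image(grid$lon, grid$lat, t(grid$values), col = pal,
                  zlim = c(0, vmax), xlab = "", ylab = "", axes = FALSE,
                  useRaster = TRUE)
  cl <- hk_coastlines()
  for (id in unique(cl$polygon)) {
    v <- cl[cl$polygon == id, ]
    graphics::polygon(v$lon, v$lat, border = "grey40", col = NA, lwd = 0.6)
  }
  graphics::points(grid$points$lon, grid$points$lat, pch = 21,
                   bg = "white", col = "grey20", cex = 0.8)
  graphics::box()
  if (!is.null(title)) graphics::title(main = title)

  # colour bar, labelled 0 -> vmax
  graphics::par(mar = c(2.5, 8, 0.5, 8))
  ramp <- matrix(seq(0, vmax, length.out = 256), ncol = 1)
  graphics::image(seq(0, vmax, length.out = 256), 1, ramp, col = pal,
                  zlim = c(0, vmax), xlab = "", ylab = "", yaxt = "n")
  invisible(out_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- composition ------------------------------------------------------

#' Cache a per-locus protein alignment for motif maps
#' @param locus locus name.
#' @param aln alignment to store; omit to read the cache.
#' @return the cached `hla_alignment` or `NULL`.
#' @export
palm_alignment_cache <- function(locus, aln = NULL) {
  key <- paste0("aln_", locus)
  if (!is.null(aln)) .hk_env[[key]] <- aln
  .hk_env[[key]]
}

#' Population Allele Locating Mapmaker
#'
#' One call per map: compute per-population point values for a variant
#' ([select_variant()]), grid them ([grid_frequencies()]) and render the
#' map ([render_map()]).  For motif maps the locus protein alignment is
#' taken from the per-session cache when `aln` is not supplied, so the
#' first map for a locus is slower than subsequent ones; pass `release` to
#' let the alignment be fetched and built from the repository.
#'
#' @inheritParams select_variant
#' @param dataset an `hk_freq_table` or `hk_hap_table`.
#' @param map_scale `TRUE` scales colours to the data maximum; `FALSE`
#'   fixes the scale at 1.0 for cross-map comparison.
#' @param color_mode,out_path,title passed to [render_map()]; `out_path =
#'   NULL` skips rendering.
#' @param release repository release used to build a missing motif
#'   alignment (requires network).
#' @param resolution,power,cutoff_km passed to [grid_frequencies()].
#' @return An object of class `hk_palm`: list with `grid`, `file` (or
#'   `NULL`) and `audit` (matched alleles, populations used and dropped,
#'   `vmax`).
#' @export
palm <- function(spec, kind = c("allele", "motif", "haplotype"), dataset,
                 aln = NULL, filter_migrant = FALSE,
                 generate_low_freq = FALSE, map_scale = TRUE,
                 color_mode = "color", out_path = NULL, title = NULL,
                 release = "Latest", resolution = 1, power = 2,
                 cutoff_km = 2000) {
  kind <- match.arg(kind)
  if (kind == "motif" && is.null(aln)) {
    locus <- parse_motif(spec)$locus
    aln <- palm_alignment_cache(locus)
    if (is.null(aln)) {
      txt <- fetch_release_file(release,
                                paste0("alignments/", locus, "_prot.txt"))
      aln <- parse_alignment(txt, "prot")
      palm_alignment_cache(locus, aln)
    }
  }
  pts <- select_variant(spec, kind, dataset, aln = aln,
                        filter_migrant = filter_migrant,
                        generate_low_freq = generate_low_freq)
  grid <- grid_frequencies(pts, resolution = resolution, power = power,
                           cutoff_km = cutoff_km,
                           scale_mode = if (map_scale) "data_max" else "unit")
  file <- NULL
  if (!is.null(out_path)) {
    file <- render_map(grid, out_path, color_mode = color_mode,
                       title = title %||% spec)
  }
  structure(list(grid = grid, file = file,
                 audit = list(spec = spec, kind = kind,
                              matched_alleles = attr(pts, "matched_alleles"),
                              populations_used = pts$population,
                              populations_dropped = attr(pts,
                                                         "dropped_migrant"),
                              vmax = grid$vmax)),
            class = "hk_palm")
}

#' @export
print.hk_palm <- function(x, ...) {
  a <- x$audit
  cat(sprintf("<hk_palm> %s (%s): %d populations (%d dropped), vmax %.4g\n",
              a$spec, a$kind, length(a$populations_used),
              length(a$populations_dropped), a$vmax))
  invisible(x)
}

#' Genotype-frequency estimates under random mating
#'
#' For two variant frequencies `f` and `g` at one position, estimates the
#' homozygote and heterozygote genotype frequencies as `f^2`, `g^2` and
#' `2*f*g`.  These are Hardy-Weinberg estimates, not observed genotype
#' counts.
#'
#' @param f,g variant frequencies in `[0, 1]`.
#' @return list with `hom_f`, `hom_g`, `het`.
#' @export
genotype_freqs <- function(f, g) {
  stopifnot(f >= 0, g >= 0, f + g <= 1 + 1e-9)
  list(hom_f = f^2, hom_g = g^2, het = 2 * f * g)
}
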