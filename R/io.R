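# bedGraph / TSV input-output for tracks, masks, hotspots and tetrad tallies

# read one bedGraph file into a dense per-chromosome value list
read_bedgraph_values <- function(path, layout) {
  lens <- layout_lengths(layout)
  vals <- lapply(lens, numeric)
  if (!file.exists(path)) stop_resectr(sprintf("file not found: %s", path))
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0L) {
    return(vals)
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  unknown <- setdiff(unique(df$seqnames), names(lens))
  if (length(unknown)) {
    stop_resectr(sprintf("bedGraph %s references unknown chromosome(s): %s",
                         path, paste(unknown, collapse = ", ")),
                 class = "resectr_format_error")
  }
  for (chr in unique(df$seqnames)) {
    sub <- df[df$seqnames == chr, , drop = FALSE]
    if (any(sub$end > lens[[chr]])) {
      stop_resectr(sprintf("bedGraph %s: interval beyond end of %s", path, chr),
                   class = "resectr_format_error")
    }
    ir <- IRanges::IRanges(start = sub$start, end = sub$end) # 1-based closed
    if (!IRanges::isDisjoint(ir)) {
      stop_resectr(sprintf("bedGraph %s: overlapping intervals on %s", path, chr),
                   class = "resectr_format_error")
    }
    cov <- IRanges::coverage(ir, weight = as.numeric(sub$score), width = lens[[chr]])
    vals[[chr]] <- as.numeric(cov)
  }
  vals
}

# write one dense value list as 4-column bedGraph; zero runs are omitted
write_bedgraph_values <- function(vals, path) {
  rows <- purrr::map_dfr(names(vals), function(chr) {
    r <- rle(vals[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    tibble(chrom = chr, start = as.integer(starts[keep]),
           end = as.integer(ends[keep]), value = r$values[keep])
  })
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' Read a strand-specific track from bedGraph files
#'
#' Reads a top/bottom bedGraph pair (or a single unstranded file) into a dense
#' [strand_track()]. Coordinates follow the bedGraph convention (0-based,
#' half-open); overlapping intervals on one strand are a format error. Writing
#' omits zero runs, so `read_track(write_track(x))` reproduces `x` exactly.
#'
#' @param layout Genome layout, see [genome_layout()].
#' @param top,bottom Paths to the top/bottom (plus/minus) strand bedGraphs.
#' @param unstranded Path to a single unstranded bedGraph (mutually exclusive
#'   with `top`/`bottom`).
#' @param units Unit label recorded on the track.
#' @return A `strand_track`.
#' @export
read_track <- function(layout, top = NULL, bottom = NULL, unstranded = NULL,
                       units = "counts") {
  check_layout(layout)
  if (!is.null(unstranded)) {
    strand_track(layout, unstranded = read_bedgraph_values(unstranded, layout),
                 units = units)
  } else {
    if (is.null(top) || is.null(bottom)) {
      stop_resectr("supply `top` and `bottom` paths, or `unstranded`")
    }
    strand_track(layout,
                 top = read_bedgraph_values(top, layout),
                 bottom = read_bedgraph_values(bottom, layout),
                 units = units)
  }
}

#' Write a track to bedGraph files
#'
#' @param track A `strand_track`.
#' @param top,bottom,unstranded Output paths matching the track's strands.
#' @return Invisibly, the paths written.
#' @export
write_track <- function(track, top = NULL, bottom = NULL, unstranded = NULL) {
  paths <- character()
  if (is_stranded(track)) {
    if (is.null(top) || is.null(bottom)) {
      stop_resectr("stranded track: supply `top` and `bottom` output paths")
    }
    write_bedgraph_values(track$values$top, top)
    write_bedgraph_values(track$values$bottom, bottom)
    paths <- c(top = top, bottom = bottom)
  } else {
    if (is.null(unstranded)) stop_resectr("unstranded track: supply `unstranded` path")
    write_bedgraph_values(track$values$unstranded, unstranded)
    paths <- c(unstranded = unstranded)
  }
  invisible(paths)
}

#' Read a BED3 interval file (e.g. a mask)
#'
#' @param path Path to a 3-column tab-separated file (chrom, start, end;
#'   0-based half-open).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = readr::cols(chrom = readr::col_character(),
                                          start = readr::col_double(),
                                          end = readr::col_double()),
                  comment = "#", progress = FALSE)
}

#' Read and write a genome layout TSV (`name  length`)
#'
#' @param path Path to a 2-column tab-separated file.
#' @return `read_layout()` returns a layout tibble; `write_layout()` the path,
#'   invisibly.
#' @export
read_layout <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", comment = "#", progress = FALSE)
  genome_layout(df$chrom, df$length)
}

#' @rdname read_layout
#' @param layout Layout tibble to write.
#' @export
write_layout <- function(layout, path) {
  check_layout(layout)
  readr::write_tsv(layout, path, col_names = FALSE)
  invisible(path)
}

#' Read and write DSB hotspot tables
#'
#' Hotspot TSVs are `chrom  start  end  heat` (0-based half-open intervals,
#' `heat` = relative DSB frequency). [as_hotspots()] derives `midpoint`,
#' `width` and a stable `hotspot_id` and is applied on read.
#'
#' @param path Path to the TSV.
#' @return `read_hotspots()` returns a hotspot tibble.
#' @export
read_hotspots <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "heat"),
                        col_types = "cddd", comment = "#", progress = FALSE)
  as_hotspots(df)
}

#' @rdname read_hotspots
#' @param hotspots Hotspot tibble to write (only `chrom`, `start`, `end`,
#'   `heat` are written).
#' @export
write_hotspots <- function(hotspots, path) {
  readr::write_tsv(hotspots[, c("chrom", "start", "end", "heat")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read and write tetrad viability tallies (`n_viable  count`)
#'
#' @param path Path to a 2-column TSV with viable-spore class (4..0) and
#'   tetrad count.
#' @return `read_tetrad_counts()` returns a tibble ordered class 4 to 0.
#' @export
read_tetrad_counts <- function(path) {
  df <- readr::read_tsv(path, col_names = c("n_viable", "count"),
                        col_types = "dd", comment = "#", progress = FALSE)
  as_tetrad_counts(df)
}

#' @rdname read_tetrad_counts
#' @param counts Tetrad count tibble to write.
#' @export
write_tetrad_counts <- function(counts, path) {
  counts <- as_tetrad_counts(counts)
  readr::write_tsv(counts, path, col_names = FALSE)
  invisible(path)
}

#' Write a simulated S1-seq dataset to disk
#'
#' Writes the strand pair as `<prefix>.plus.bedgraph` / `<prefix>.minus.bedgraph`,
#' the hotspot table as `<prefix>.hotspots.tsv`, the layout as
#' `<prefix>.layout.tsv`, and a YAML sidecar `<prefix>.yaml` recording all
#' generator parameters and the seed.
#'
#' @param sim Result of [simulate_s1seq()] or [simulate_s1seq_direct()].
#' @param hotspots Hotspot tibble used for the simulation.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_s1seq_dataset <- function(sim, hotspots, dir, prefix = "s1seq") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  write_track(sim$track, top = p(".plus.bedgraph"), bottom = p(".minus.bedgraph"))
  write_hotspots(hotspots, p(".hotspots.tsv"))
  write_layout(sim$track$layout, p(".layout.tsv"))
  yaml::write_yaml(sim$params, p(".yaml"))
  invisible(c(plus = p(".plus.bedgraph"), minus = p(".minus.bedgraph"),
              hotspots = p(".hotspots.tsv"), layout = p(".layout.tsv"),
              params = p(".yaml")))
}
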