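# sim_io: field initialization, VTI / CellInfo writers, simulation driver.

#' Build the initial global field from configured placements
#'
#' Supported shapes: `single` (one voxel), `cube` (filled cube; with
#' `cell_edge` set, tiled into equal cubic cells), `sphere` (filled digital
#' ball; with `cell_edge`, tiled into cells clipped to the ball).  Cells get
#' sequential ids from 1; overlapping placements are a configuration error.
#'
#' @param config A [cpm_config()].
#' @param layout Optional [block_layout()] (derived from the config if
#'   omitted).
#' @return List with `field` (global integer array), `ids` and `type`
#'   (type index per cell).
#' @export
init_field <- function(config, layout = NULL) {
  if (!inherits(config, "cpm_config")) config <- cpm_config(config)
  size <- config$domain$size
  field <- array(0L, dim = size)
  ids <- integer(0)
  type <- integer(0)
  next_id <- 1L
  place <- function(vox, id, p) {
    # vox: matrix of 0-based global coords
    if (any(vox < 0) || any(vox[, 1] >= size[1]) || any(vox[, 2] >= size[2]) ||
        any(vox[, 3] >= size[3])) {
      cfg_err(p, "placement outside the domain")
    }
    idx <- vox + 1L
    if (any(field[idx] != 0L)) cfg_err(p, "overlapping placements")
    field[idx] <<- id
  }
  for (k in seq_along(config$init)) {
    pl <- config$init[[k]]
    p <- paste0("init[", k, "]")
    ti <- match(pl$type, config$types$name)
    if (pl$shape == "single") {
      pos <- as.integer(unlist(pl$position))
      if (length(pos) != 3) cfg_err(paste0(p, ".position"), "required triple")
      place(matrix(pos, 1), next_id, p)
      ids <- c(ids, next_id); type <- c(type, ti); next_id <- next_id + 1L
    } else {
      if (pl$shape == "cube") {
        corner <- as.integer(unlist(pl$corner))
        edge <- as.integer(pl$size)
        region <- as.matrix(expand.grid(corner[1] + seq_len(edge) - 1L,
                                        corner[2] + seq_len(edge) - 1L,
                                        corner[3] + seq_len(edge) - 1L))
      } else {  # sphere
        ctr <- as.numeric(unlist(pl$center))
        r <- as.numeric(pl$radius)
        lo <- floor(ctr - r); hi <- ceiling(ctr + r)
        region <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
        keep <- rowSums(sweep(region, 2, ctr)^2) <= r^2
        region <- region[keep, , drop = FALSE]
      }
      if (is.null(pl$cell_edge)) {
        place(region, next_id, p)
        ids <- c(ids, next_id); type <- c(type, ti); next_id <- next_id + 1L
      } else {
        ce <- as.integer(pl$cell_edge)
        base <- apply(region, 2, min)
        tile <- floor(sweep(region, 2, base) / ce)
        key <- tile[, 1] + 1000L * tile[, 2] + 1000000L * tile[, 3]
        for (tk in sort(unique(key))) {
          vox <- region[key == tk, , drop = FALSE]
          place(vox, next_id, p)
          ids <- c(ids, next_id); type <- c(type, ti); next_id <- next_id + 1L
        }
      }
    }
  }
  list(field = field, ids = ids, type = type)
}

#' Write a label field as a VTK ImageData (.vti) file
#'
#' Standard VTK XML ImageData with appended raw binary encoding, holding the
#' whole domain as point data named `cellID` (Int32, or Int64 when requested
#' for very large cell counts).  Readable by VTK-based viewers such as
#' ParaView.
#'
#' @param field Global 3D integer label array.
#' @param path Output file path.
#' @param int64 Write 64-bit integers instead of 32-bit.
#' @return `path`, invisibly.
#' @export
write_vti <- function(field, path, int64 = FALSE) {
  dm <- dim(field)
  ext <- sprintf("0 %d 0 %d 0 %d", dm[1] - 1L, dm[2] - 1L, dm[3] - 1L)
  dtype <- if (int64) "Int64" else "Int32"
  bytes_per <- if (int64) 8L else 4L
  nbytes <- length(field) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="ImageData" version="1.0" byte_order="LittleEndian" header_type="UInt32">\n',
    '  <ImageData WholeExtent="', ext, '" Origin="0 0 0" Spacing="1 1 1">\n',
    '    <Piece Extent="', ext, '">\n',
    '      <PointData Scalars="cellID">\n',
    '        <DataArray type="', dtype, '" Name="cellID" format="appended" offset="0"/>\n',
    '      </PointData>\n',
    '      <CellData/>\n',
    '    </Piece>\n',
    '  </ImageData>\n',
    '  <AppendedData encoding="raw">\n_')
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  if (int64) {
    # values are non-negative and fit 32 bits in practice: low word + zero
    # high word in little-endian order
    v <- as.vector(field)
    words <- rbind(as.integer(v), integer(length(v)))
    writeBin(as.integer(words), con, size = 4, endian = "little")
  } else {
    writeBin(as.vector(field), con, size = 4, endian = "little")
  }
  writeChar("\n  </AppendedData>\n</VTKFile>\n", con, eos = NULL)
  invisible(path)
}

#' Read back a VTI file written by [write_vti()]
#'
#' @param path Path to the .vti file.
#' @return The integer label array.
#' @export
read_vti <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # the payload delimiter is the first '_' directly following the '>' of the
  # AppendedData element (attribute names also contain underscores)
  ws <- as.raw(c(0x20, 0x0a, 0x0d, 0x09))
  mark0 <- NA_integer_
  for (m in which(raw == charToRaw("_"))) {
    k <- m - 1L
    while (k > 0L && raw[k] %in% ws) k <- k - 1L
    if (k > 0L && raw[k] == charToRaw(">")) { mark0 <- m; break }
  }
  txt <- rawToChar(raw[seq_len(mark0 - 1L)])
  ext <- regmatches(txt, regexpr('WholeExtent="[^"]+"', txt))
  nums <- as.integer(strsplit(sub('WholeExtent="([^"]+)"', "\\1", ext), " ")[[1]])
  dm <- c(nums[2] - nums[1] + 1L, nums[4] - nums[3] + 1L, nums[6] - nums[5] + 1L)
  dtype <- regmatches(txt, regexpr('DataArray type="[^"]+"', txt))
  int64 <- grepl("Int64", dtype)
  nbytes <- readBin(raw[mark0 + 1:4], "integer", 1, size = 4, endian = "little")
  payload <- raw[mark0 + 4 + seq_len(nbytes)]
  if (int64) {
    words <- readBin(payload, "integer", nbytes / 4, size = 4, endian = "little")
    vals <- words[seq(1, length(words), by = 2)]
  } else {
    vals <- readBin(payload, "integer", nbytes / 4, size = 4, endian = "little")
  }
  array(vals, dim = dm)
}

#' Write the per-cell CellInfo CSV
#'
#' One row per live cell, emitted by the block owning the cell's center of
#' mass (a block-spanning cell appears exactly once): id, type name, age (in
#' MCS), volume, surface, integer center-of-mass voxel and one column per
#' signal channel.
#'
#' @param sim A [cpm_sim()] environment.
#' @param path Output file path.
#' @return The data.frame written, invisibly.
#' @export
write_cellinfo_csv <- function(sim, path) {
  df <- cellinfo(sim)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Per-cell summary table of a running simulation
#'
#' @param sim A [cpm_sim()] environment.
#' @return data.frame with one row per live cell (see
#'   [write_cellinfo_csv()]).
#' @export
cellinfo <- function(sim) {
  reg <- cell_registry(sim)
  keep <- reg$v > 0
  n <- sum(keep)
  com <- matrix(0L, n, 3)
  ids <- reg$ids[keep]
  idx <- which(keep)
  for (r in seq_len(n)) {
    i <- idx[r]
    com[r, ] <- com_voxel(reg$cx[i], reg$cy[i], reg$cz[i], reg$v[i], sim$cfg$domain$size)
  }
  df <- data.frame(id = ids, type = sim$types$name[reg$type[keep]],
                   age = sim$mcs - reg$birth[keep],
                   volume = reg$v[keep], surface = reg$s[keep],
                   com_x = com[, 1], com_y = com[, 2], com_z = com[, 3])
  if (sim$nchan) {
    sg <- t(reg$sig[, keep, drop = FALSE])
    colnames(sg) <- paste0("signal_", sim$cfg$signals)
    df <- cbind(df, sg)
  }
  df
}

output_action <- function(sim) {
  o <- sim$cfg$output
  if (o$every <= 0L) return(invisible(sim))
  cyc <- current_cycle(sim)
  if (cyc %% o$every != 0L) return(invisible(sim))
  if (!dir.exists(o$path)) dir.create(o$path, recursive = TRUE)
  if (o$vti) {
    write_vti(reassemble_field(sim$blocks, sim$layout),
              file.path(o$path, sprintf("frame_%06d.vti", cyc)), int64 = o$int64)
  }
  if (o$csv) {
    write_cellinfo_csv(sim, file.path(o$path, sprintf("cellinfo_%06d.csv", cyc)))
  }
  invisible(sim)
}

#' Run a complete simulation
#'
#' Convenience driver: builds the simulation from a configuration (path or
#' object), seeds the R RNG (cell events) and the per-block streams, runs
#' the requested number of color cycles and writes the configured output
#' frames.
#'
#' @param config Path to a JSON configuration, or a [cpm_config()] object.
#' @param cycles Number of color cycles to run.
#' @param seed Optional seed overriding the config.
#' @param out Optional output directory overriding the config.
#' @return The final `cpm_sim` environment, invisibly.
#' @export
run_simulation <- function(config, cycles, seed = NULL, out = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "cpm_config")) config <- cpm_config(config)
  if (!is.null(out)) config$output$path <- out
  sim_seed <- if (is.null(seed)) config$domain$seed else as.integer(seed)
  set.seed(sim_seed)
  sim <- cpm_sim(config, seed = sim_seed)
  output_action(sim)  # frame at cycle 0 if configured
  run_cycles(sim, cycles)
  invisible(sim)
}
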