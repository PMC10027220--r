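#' Gridded file I/O
#'
#' Fields and emission inventories are stored in a self-describing plain-text
#' gridded format: a header with the grid coordinate variables, units and any
#' categorical dimensions (month, sector, species), followed by a `data:`
#' block holding the values with full double precision (`%.17g`, so a
#' write-then-read roundtrip is bit-exact). The data block is written in the
#' canonical internal order (cell, month, sector, species); files whose
#' header declares a different `order:` are permuted to canonical order on
#' read. Files missing coordinate variables or the units attribute are
#' rejected with a message naming the missing element.
#'
#' @param x a `field` or `emission_inventory`
#' @param path output path
#' @return `write_gridded` returns `path` invisibly; `read_gridded` returns
#'   the reconstructed object.
#' @name gridded_io
NULL

fmt_nums <- function(v) {
  s <- sprintf("%.17g", v)
  n <- length(s)
  rows <- split(s, (seq_len(n) - 1L) %/% 6L)
  vapply(rows, paste, "", collapse = " ")
}

#' @rdname gridded_io
#' @export
write_gridded <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("pmadjoint-gridded 1")
  if (inherits(x, "field")) {
    g <- x$grid
    v <- x$values
    dims <- if (is.null(dim(v))) "cell" else switch(as.character(length(dim(v))),
      "2" = "cell month",
      stop("unsupported field array rank for I/O")
    )
    wl("kind: field")
    wl("units: ", x$units)
    wl("dims: ", dims)
  } else if (inherits(x, "emission_inventory")) {
    g <- x$grid
    v <- x$mass
    wl("kind: inventory")
    wl("units: kg")
    wl("dims: cell month sector species")
    wl("year: ", x$year)
    wl("sectors: ", paste(names(x$sector_map), collapse = ","))
    wl("main_sectors: ", paste(unname(x$sector_map), collapse = ","))
    wl("species: ", paste(x$species, collapse = ","))
  } else {
    stop("write_gridded handles field and emission_inventory objects")
  }
  wl("nlat: ", g$nlat)
  wl("nlon: ", g$nlon)
  wl("lat: ", paste(sprintf("%.17g", g$lat), collapse = " "))
  wl("lon: ", paste(sprintf("%.17g", g$lon), collapse = " "))
  wl("order: cell month sector species")
  wl("data:")
  writeLines(fmt_nums(as.numeric(v)), con)
  invisible(path)
}

#' @rdname gridded_io
#' @export
read_gridded <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "pmadjoint-gridded")) {
    stop("not a pmadjoint gridded file: ", path)
  }
  data_at <- match("data:", lines)
  if (is.na(data_at)) stop("missing element 'data:' in ", path)
  hdr <- lines[2:(data_at - 1)]
  kv <- regmatches(hdr, regexpr("^[a-z_]+:", hdr))
  keys <- sub(":$", "", kv)
  vals <- trimws(mapply(function(l, k) sub(paste0("^", k, ":"), "", l), hdr, keys))
  names(vals) <- keys
  need <- function(k) {
    if (!k %in% names(vals)) stop("missing element '", k, "' in ", path)
    vals[[k]]
  }
  kind <- need("kind")
  units <- need("units")
  lat <- scan(text = need("lat"), quiet = TRUE)
  lon <- scan(text = need("lon"), quiet = TRUE)
  nlat <- as.integer(need("nlat"))
  nlon <- as.integer(need("nlon"))
  if (length(lat) != nlat || length(lon) != nlon) {
    stop("coordinate variables do not match nlat/nlon in ", path)
  }
  grid <- grid_spec(lat, lon)
  vals_num <- scan(text = paste(lines[(data_at + 1):length(lines)], collapse = " "),
                   quiet = TRUE)
  dims <- strsplit(need("dims"), "[ ]+")[[1]]
  order_in <- strsplit(if ("order" %in% names(vals)) vals[["order"]] else "cell month sector species",
                       "[ ]+")[[1]]
  if (kind == "field") {
    if (identical(dims, "cell")) {
      if (length(vals_num) != grid$ncell) stop("data length mismatch in ", path)
      return(field(grid, vals_num, units))
    }
    dn <- c(cell = grid$ncell, month = 12L)
    arr <- array(vals_num, unname(dn[intersect(order_in, dims)]))
    arr <- aperm(arr, match(c("cell", "month"), intersect(order_in, dims)))
    return(field(grid, matrix(arr, grid$ncell, 12), units))
  }
  if (kind == "inventory") {
    sectors <- strsplit(need("sectors"), ",")[[1]]
    mains <- strsplit(need("main_sectors"), ",")[[1]]
    species <- strsplit(need("species"), ",")[[1]]
    smap <- stats::setNames(mains, sectors)
    dn <- c(cell = grid$ncell, month = 12L,
            sector = length(sectors), species = length(species))
    ord <- intersect(order_in, names(dn))
    arr <- array(vals_num, unname(dn[ord]))
    arr <- aperm(arr, match(names(dn), ord))
    return(emission_inventory(grid, arr, smap, species, need("year")))
  }
  stop("unknown kind '", kind, "' in ", path)
}

#' Write a summary table as CSV (UTF-8, header row)
#' @param df data.frame
#' @param path output path
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a summary table written by [write_table_csv()]
#' @param path CSV path
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
}
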