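#' Rate fields: population rates over grid and stimulus size
#'
#' A rate field stores the mean rate of each population at every grid node
#' for every stimulus size, as a 3D array `values[population, node, size]`
#' together with the grid and the (strictly increasing) stimulus sizes.
#' Both the observed data handed to the fitter and the model's predicted
#' steady states use this container; external drives (`L4`, `LM`, `R`) use
#' it too, just with source populations.
#'
#' @param values 3D numeric array `[n_pop, n_nodes, n_sizes]`, all entries
#'   >= 0, with population dimnames on the first margin; or a list of
#'   `n_nodes x n_sizes` matrices named by population.
#' @param grid the [retinotopic_grid()] the nodes refer to.
#' @param sizes strictly increasing stimulus sizes in degrees.
#' @return object of class `ssn_rate_field` with elements `values`,
#'   `populations`, `grid`, `sizes`.
#' @export
rate_field <- function(values, grid, sizes) {
  if (is.list(values)) {
    pops <- names(values)
    arr <- array(0, c(length(pops), grid$n_nodes, length(sizes)),
                 dimnames = list(pops, NULL, NULL))
    for (p in pops) arr[p, , ] <- values[[p]]
    values <- arr
  }
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  pops <- dimnames(values)[[1]]
  if (is.null(pops)) stop("values needs population dimnames on margin 1")
  if (dim(values)[2] != grid$n_nodes) {
    stop("node dimension does not match the grid")
  }
  if (dim(values)[3] != length(sizes)) {
    stop("size dimension does not match sizes")
  }
  if (any(diff(sizes) <= 0)) stop("stimulus sizes must be strictly increasing")
  if (any(values < 0)) stop("rates must be non-negative")
  structure(list(values = values, populations = pops, grid = grid,
                 sizes = as.numeric(sizes)),
            class = "ssn_rate_field")
}

#' @export
print.ssn_rate_field <- function(x, ...) {
  cat(sprintf("<ssn_rate_field> %s | %d nodes | sizes %s deg\n",
              paste(x$populations, collapse = ","), x$grid$n_nodes,
              paste(x$sizes, collapse = ",")))
  invisible(x)
}

# convenience: matrix n_nodes x n_sizes for one population
field_pop <- function(rf, pop) {
  m <- rf$values[pop, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Size-tuning curve at the stimulus center
#'
#' The response of the unit whose receptive field sits closest to the
#' stimulus center (0 deg retinotopy), as a function of stimulus size;
#' surround suppression shows as a decline beyond a peak.
#'
#' @param rf an [rate_field()].
#' @param pop population name.
#' @return numeric vector over `rf$sizes`.
#' @export
size_tuning <- function(rf, pop) {
  rf$values[pop, center_node(rf$grid), ]
}

#' Write / read a rate-field table
#'
#' Long-format CSV with header exactly
#' `population,x_deg,y_deg,stimulus_size_deg,rate`, UTF-8, '.' decimal.
#' Values are written with 17 significant digits so the write/read round
#' trip is bit exact. Reading rejects duplicate
#' (population, x, y, size) keys and requires the positions to form a
#' complete regular grid.
#'
#' @param rf an [rate_field()].
#' @param path file path.
#' @param populations optional expected population set for validation on
#'   read (e.g. `ssn_recurrent_types()`).
#' @return `read_rate_table` returns an `ssn_rate_field`.
#' @export
write_rate_table <- function(rf, path) {
  g <- rf$grid
  long <- data.frame(
    population = rep(rf$populations,
                     times = g$n_nodes * length(rf$sizes)),
    x_deg = rep(rep(g$coords[, 1], each = length(rf$populations)),
                times = length(rf$sizes)),
    y_deg = rep(rep(g$coords[, 2], each = length(rf$populations)),
                times = length(rf$sizes)),
    stimulus_size_deg = rep(rf$sizes,
                            each = length(rf$populations) * g$n_nodes),
    rate = as.vector(rf$values)
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("population,x_deg,y_deg,stimulus_size_deg,rate", con)
  if (nrow(long)) {
    lines <- paste(long$population,
                   format(long$x_deg, digits = 17, trim = TRUE),
                   format(long$y_deg, digits = 17, trim = TRUE),
                   format(long$stimulus_size_deg, digits = 17, trim = TRUE),
                   format(long$rate, digits = 17, trim = TRUE),
                   sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path, populations = NULL) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric",
                                             "numeric", "numeric", "numeric"),
                        encoding = "UTF-8")
  expected <- c("population", "x_deg", "y_deg", "stimulus_size_deg", "rate")
  if (!identical(names(df), expected)) {
    stop("rate table must have header ", paste(expected, collapse = ","))
  }
  pops <- unique(df$population)
  if (!is.null(populations) && !all(pops %in% populations)) {
    stop("unknown population labels: ",
         paste(setdiff(pops, populations), collapse = ", "))
  }
  if (nrow(df) == 0) {
    # empty table: header only; degenerate but valid
    g <- retinotopic_grid(2, 2, 1)
    vals <- array(0, c(0, g$n_nodes, 0), dimnames = list(character(0)))
    return(structure(list(values = vals, populations = character(0),
                          grid = g, sizes = numeric(0)),
                     class = "ssn_rate_field"))
  }
  key <- paste(df$population, df$x_deg, df$y_deg, df$stimulus_size_deg)
  if (anyDuplicated(key)) stop("duplicate (population, x, y, size) rows")
  xs <- sort(unique(df$x_deg)); ys <- sort(unique(df$y_deg))
  dx <- unique(round(diff(xs), 10)); dy <- unique(round(diff(ys), 10))
  if (length(dx) != 1 || length(dy) != 1 || !isTRUE(all.equal(dx, dy))) {
    stop("positions do not form a regular square-spaced grid")
  }
  g <- retinotopic_grid(length(xs), length(ys), dx)
  sizes <- sort(unique(df$stimulus_size_deg))
  arr <- array(NA_real_, c(length(pops), g$n_nodes, length(sizes)),
               dimnames = list(pops, NULL, NULL))
  ix <- match(round(df$x_deg, 10), round(xs, 10))
  iy <- match(round(df$y_deg, 10), round(ys, 10))
  node <- (iy - 1L) * g$n_x + ix
  isz <- match(df$stimulus_size_deg, sizes)
  ip <- match(df$population, pops)
  arr[cbind(ip, node, isz)] <- df$rate
  if (anyNA(arr)) stop("incomplete rate table: missing grid/size entries")
  rate_field(arr, g, sizes)
}
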