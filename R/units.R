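#' @importFrom stats setNames runif rnorm
#' @importFrom utils read.delim write.table head tail
NULL

# Seven SI base quantities, in fixed order. A Dimension is an integer vector
# of exponents over these.
.si_base <- c("mass", "length", "time", "current", "temperature",
              "amount", "luminosity")

#' Create a dimension from SI base-quantity exponents
#'
#' Dimensions are integer exponent vectors over the seven SI base
#' quantities. They support product/quotient/power algebra and are used to
#' check that every parameter binding and every expression in a dynamics
#' template is dimensionally consistent.
#'
#' @param mass,length,time,current,temperature,amount,luminosity integer
#'   exponents.
#' @return An object of class `wl_dimension`.
#' @export
#' @examples
#' voltage <- dimension(mass = 1, length = 2, time = -3, current = -1)
#' dim_multiply(voltage, dimension(current = 1))  # power
dimension <- function(mass = 0L, length = 0L, time = 0L, current = 0L,
                      temperature = 0L, amount = 0L, luminosity = 0L) {
  e <- c(mass, length, time, current, temperature, amount, luminosity)
  if (any(e != round(e))) stop("dimension exponents must be integers")
  structure(setNames(as.integer(e), .si_base), class = "wl_dimension")
}

#' @export
print.wl_dimension <- function(x, ...) {
  nz <- x[x != 0L]
  if (length(nz) == 0L) {
    cat("<dimension: dimensionless>\n")
  } else {
    cat("<dimension:", paste0(names(nz), "^", nz, collapse = " "), ">\n")
  }
  invisible(x)
}

#' Dimension algebra
#'
#' Product, quotient and integer power of dimensions.
#'
#' @param a,b `wl_dimension` objects.
#' @param k integer power.
#' @return A `wl_dimension`.
#' @export
dim_multiply <- function(a, b) {
  structure(setNames(as.integer(unclass(a) + unclass(b)), .si_base),
            class = "wl_dimension")
}

#' @rdname dim_multiply
#' @export
dim_divide <- function(a, b) {
  structure(setNames(as.integer(unclass(a) - unclass(b)), .si_base),
            class = "wl_dimension")
}

#' @rdname dim_multiply
#' @export
dim_power <- function(a, k) {
  if (k != round(k)) stop("dimension power must be an integer")
  structure(setNames(as.integer(unclass(a) * as.integer(k)), .si_base),
            class = "wl_dimension")
}

#' @rdname dim_multiply
#' @export
dim_equal <- function(a, b) all(unclass(a) == unclass(b))

dim_is_dimensionless <- function(a) all(unclass(a) == 0L)

#' Named dimensions used by the core model library
#'
#' @return A named list of `wl_dimension` objects.
#' @export
standard_dimensions <- function() {
  list(
    dimensionless = dimension(),
    time          = dimension(time = 1),
    per_time      = dimension(time = -1),
    voltage       = dimension(mass = 1, length = 2, time = -3, current = -1),
    current       = dimension(current = 1),
    conductance   = dimension(mass = -1, length = -2, time = 3, current = 2),
    capacitance   = dimension(mass = -1, length = -2, time = 4, current = 2)
  )
}

# Fixed unit table: symbol -> (dimension name, power-of-ten scale to SI).
.unit_table <- list(
  none   = list(dimension = "dimensionless", power = 0L),
  s      = list(dimension = "time",          power = 0L),
  ms     = list(dimension = "time",          power = -3L),
  per_s  = list(dimension = "per_time",      power = 0L),
  per_ms = list(dimension = "per_time",      power = 3L),
  V      = list(dimension = "voltage",       power = 0L),
  mV     = list(dimension = "voltage",       power = -3L),
  A      = list(dimension = "current",       power = 0L),
  nA     = list(dimension = "current",       power = -9L),
  pA     = list(dimension = "current",       power = -12L),
  S      = list(dimension = "conductance",   power = 0L),
  uS     = list(dimension = "conductance",   power = -6L),
  nS     = list(dimension = "conductance",   power = -9L),
  F      = list(dimension = "capacitance",   power = 0L),
  uF     = list(dimension = "capacitance",   power = -6L),
  nF     = list(dimension = "capacitance",   power = -9L)
)

#' Units known to the model system
#'
#' Each unit carries a dimension name and a power-of-ten scale to SI, used
#' both for dimensional checking of parameter bindings and for converting
#' bound values to SI before simulation.
#'
#' @return A data.frame with columns `symbol`, `dimension`, `power`.
#' @export
unit_table <- function() {
  data.frame(
    symbol = names(.unit_table),
    dimension = vapply(.unit_table, `[[`, "", "dimension"),
    power = vapply(.unit_table, function(u) as.integer(u$power), 0L),
    row.names = NULL
  )
}

unit_info <- function(symbol) {
  u <- .unit_table[[symbol]]
  if (is.null(u)) stop("unknown unit: '", symbol, "'", call. = FALSE)
  u
}

unit_dimension <- function(symbol) {
  standard_dimensions()[[unit_info(symbol)$dimension]]
}

# "0.2 nF", "-65mV", "5" (dimensionless) -> list(value, unit)
parse_quantity <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec(
    "^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*([A-Za-z_]*)$", text))[[1]]
  if (length(m) == 0L) stop("cannot parse quantity: '", text, "'", call. = FALSE)
  unit <- if (nzchar(m[3])) m[3] else "none"
  unit_info(unit)  # validates
  list(value = as.numeric(m[2]), unit = unit)
}

# value in declared unit -> SI
quantity_to_si <- function(value, unit) value * 10^unit_info(unit)$power
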