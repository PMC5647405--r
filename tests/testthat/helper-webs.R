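# small webs built in code for the tests

# two-group toy: producer grazed by one fished consumer; EE solvable by hand
toy_web <- function(consumer_catch = 0.5) {
  g <- data.frame(
    name = c("prod", "cons"),
    is_producer = c(TRUE, FALSE),
    is_detritus = FALSE,
    biomass = c(10, 1),
    pb = c(10, 1),
    qb = c(0, 5),
    ee = NA_real_,
    catch = c(0, consumer_catch))
  d <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(g$name, g$name))
  food_web(g, d)
}

# three-group chain with detritus closure and a thermal niche on the consumer
chain_web <- function() make_web(synthetic_spec(n_groups = 3))

default_web <- function() make_web(synthetic_spec())

# a fake trajectory object for objective-function unit tests
fake_run <- function(years, biomass, catch = biomass) {
  structure(list(years = years, biomass = biomass, catch = catch,
                 final_state = biomass[nrow(biomass), ],
                 t_rel = rep(1, ncol(biomass))),
            class = "ecosim_run")
}

# nesting of configurations: within the candidate set (fishing rows only),
# adding an estimated predator can only reduce the minimum SS, and adding
# the first or second anomaly knot likewise (a third knot repositions the
# earlier ones, so that family is not strictly nested)
nested_chains_ok <- function(fit, tol = 1e-6) {
  rows <- Filter(function(r) identical(r$forcing_used, "fishing"), fit$results)
  nv <- vapply(rows, `[[`, numeric(1), "n_v")
  ns <- vapply(rows, `[[`, numeric(1), "n_spline")
  ss <- vapply(rows, `[[`, numeric(1), "ss")
  mono <- function(m) all(diff(m) <= tol * abs(m[-length(m)]) + 1e-9)
  ok <- TRUE
  for (s in unique(ns)) {
    m <- tapply(ss[ns == s], nv[ns == s], min)
    ok <- ok && mono(m)
  }
  for (v in unique(nv)) {
    m <- tapply(ss[nv == v], ns[nv == v], min)
    m <- m[names(m) %in% c("0", "1", "2")]
    ok <- ok && mono(m)
  }
  ok
}
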