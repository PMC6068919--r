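# Flat key-value configuration files for parameter sets. JSON is used
# so that doubles round-trip at full precision.

#' Read and write game-parameter configuration files
#'
#' The file is a flat JSON object with keys `N`, `pi`, `c`, `theta`,
#' `p`. Values are written at full double precision, so
#' `read_game_config(write_game_config(params, path))` reproduces
#' `params` exactly.
#'
#' @param params A [game_parameters()] object.
#' @param path File path.
#' @return `write_game_config()` returns `path` invisibly;
#'   `read_game_config()` returns a validated [game_parameters()]
#'   object.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' write_game_config(game_parameters(100, 1e6, 0.5e6, 0.75, 0.5), cfg)
#' read_game_config(cfg)
#' @export
write_game_config <- function(params, path) {
  .check_params(params)
  jsonlite::write_json(
    list(N = params$N, pi = params$pi, c = params$c,
         theta = params$theta, p = params$p),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_game_config
#' @export
read_game_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("N", "pi", "c", "theta", "p")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop(sprintf("config file is missing keys: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  game_parameters(N = as.numeric(cfg$N), pi = as.numeric(cfg$pi),
                  c = as.numeric(cfg$c), theta = as.numeric(cfg$theta),
                  p = as.numeric(cfg$p))
}
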