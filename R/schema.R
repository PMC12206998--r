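#' Food and beverage group schema
#'
#' The 13 demand groups used throughout the package: eight beverage groups,
#' four food groups and a residual numeraire covering all other at-home food
#' and beverage purchases. Beverage groups subject to the sugar split are
#' divided at 4 g of sugar per 100 ml (low-sugar: up to 4 g; high-sugar: over
#' 4 g), mirroring the sugar threshold of South Africa's Health Promotion Levy.
#'
#' @param numeraire_label label for the residual group.
#' @return An object of class `group_schema`: a list with `groups` (ordered
#'   character vector of 13 labels), `numeraire_index` (13), and the sugar
#'   threshold in g/100 ml.
#' @export
group_schema <- function(numeraire_label = "numeraire") {
  groups <- c(
    "bottled water",
    "100% juice",
    "LS soft drinks",
    "HS soft drinks",
    "coffee and tea",
    "milk and LS dairy drinks and alternatives",
    "HS dairy drinks and alternatives",
    "alcoholic beverages",
    "chocolate and candy",
    "desserts",
    "snacks",
    "FVNS",
    numeraire_label
  )
  stopifnot(!anyDuplicated(groups))
  structure(
    list(groups = groups, numeraire_index = 13L, sugar_threshold = 4),
    class = "group_schema"
  )
}

#' @export
print.group_schema <- function(x, ...) {
  cat("Group schema:", length(x$groups), "groups, numeraire =",
      x$groups[x$numeraire_index], "\n")
  for (i in seq_along(x$groups)) cat(sprintf("  %2d. %s\n", i, x$groups[i]))
  invisible(x)
}

# Item-type vocabulary recognised by classify_item(). Types marked sugar_split
# require a sugar content to be classified.
item_vocabulary <- function() {
  data.frame(
    item_type = c("bottled_water", "flavored_water", "juice_100", "soft_drink",
                  "coffee_tea", "coffee_tea_drink", "milk", "dairy_drink",
                  "alcohol", "chocolate_candy", "dessert", "snack", "fvns",
                  "other_food", "other_beverage"),
    sugar_split = c(FALSE, TRUE, FALSE, TRUE,
                    FALSE, TRUE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Classify a purchased item into one of the 13 demand groups
#'
#' Beverages subject to the sugar split are divided at 4 g of sugar per
#' 100 ml: up to 4 g goes to the low-sugar group, over 4 g to the high-sugar
#' group. Two exceptions apply. Flavored water and ready-to-drink coffee/tea
#' with over 4 g/100 ml that are not taxable are moved to the numeraire
#' (taxable ones are treated as high-sugar soft drinks). Soft drinks and dairy
#' drinks with over 4 g/100 ml are always kept in the corresponding high-sugar
#' group, taxable or not. The four food categories map directly to their
#' groups; every other recognised type falls into the numeraire.
#'
#' @param item_type character scalar from the recognised vocabulary (see
#'   `item_vocabulary()`); unrecognised non-beverage types map to the
#'   numeraire.
#' @param sugar_per_100ml sugar content in grams per 100 ml, or `NA` when
#'   unknown. Required (non-`NA`) for types subject to the sugar split.
#' @param taxable_flag logical: is the item subject to the sugar levy?
#' @return Integer group index in 1..13.
#' @seealso [group_schema()]
#' @export
classify_item <- function(item_type, sugar_per_100ml = NA_real_,
                          taxable_flag = FALSE) {
  stopifnot(length(item_type) == 1L)
  g <- classify_vec(item_type, sugar_per_100ml, taxable_flag)
  if (is.na(g)) {
    stopf("item_type '%s' requires the sugar split but sugar_per_100ml is missing",
          item_type)
  }
  g
}

# Vectorised classification; returns NA for sugar-unclassifiable beverages.
classify_vec <- function(item_type, sugar, taxable) {
  n <- length(item_type)
  sugar <- rep_len(as.numeric(sugar), n)
  taxable <- rep_len(as.logical(taxable), n)
  out <- rep.int(13L, n)
  hs <- sugar > 4           # NA when sugar missing

  set_group <- function(out, idx, val) { out[idx] <- val; out }

  out[item_type == "bottled_water"] <- 1L
  fw <- item_type == "flavored_water"
  out[fw & !is.na(hs) & !hs] <- 1L
  out[fw & !is.na(hs) & hs & taxable] <- 4L
  out[fw & !is.na(hs) & hs & !taxable] <- 13L
  out[fw & is.na(hs)] <- NA_integer_

  out[item_type == "juice_100"] <- 2L

  sd_ <- item_type == "soft_drink"
  out[sd_ & !is.na(hs) & !hs] <- 3L
  out[sd_ & !is.na(hs) & hs] <- 4L   # taxable or not: kept in HS soft drinks
  out[sd_ & is.na(hs)] <- NA_integer_

  out[item_type == "coffee_tea"] <- 5L
  ct <- item_type == "coffee_tea_drink"
  out[ct & !is.na(hs) & !hs] <- 5L
  out[ct & !is.na(hs) & hs & taxable] <- 4L
  out[ct & !is.na(hs) & hs & !taxable] <- 13L
  out[ct & is.na(hs)] <- NA_integer_

  out[item_type == "milk"] <- 6L
  dd <- item_type == "dairy_drink"
  out[dd & !is.na(hs) & !hs] <- 6L
  out[dd & !is.na(hs) & hs] <- 7L    # taxable or not: kept in HS dairy drinks
  out[dd & is.na(hs)] <- NA_integer_

  out[item_type == "alcohol"] <- 8L
  out[item_type == "chocolate_candy"] <- 9L
  out[item_type == "dessert"] <- 10L
  out[item_type == "snack"] <- 11L
  out[item_type == "fvns"] <- 12L
  # other_food / other_beverage / unrecognised -> numeraire (13L default)
  out
}
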