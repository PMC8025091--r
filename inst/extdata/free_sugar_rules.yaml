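# Free-sugar estimation rules (category -> fraction of declared sugars
# counted as free sugars).
#
# Products that declare added sugars use that value directly. Otherwise
# the declared total sugars are multiplied by the category fraction; when
# requires_added_sugar_keyword is true the fraction applies only if an
# added-sugar keyword was found in the ingredient list (else 0 g free).
# Products declaring neither total nor added sugars are indeterminate.
#
# basis: "total" applies the fraction to declared total sugars (default);
# "added" applies it to declared added sugars when those are present.
basis: total
default:
  fraction_with_keyword: 1.0
  fraction_without_keyword: 0.0
categories:
  # beverages with no or minimal naturally occurring sugars: everything
  # declared is counted as free
  sweetened_beverages:       {fraction: 1.0, requires_added_sugar_keyword: false}
  concentrated_juices:       {fraction: 1.0, requires_added_sugar_keyword: false}
  candies_sweets:            {fraction: 1.0, requires_added_sugar_keyword: false}
  table_sugar:               {fraction: 1.0, requires_added_sugar_keyword: false}
  # milk and yogurt: half of the declared sugars counted as free, and only
  # when some type of sugar appears in the ingredient list (lactose and
  # other intrinsic milk sugars are not free sugars)
  sweetened_dairy_beverages: {fraction: 0.5, requires_added_sugar_keyword: true}
  plain_dairy:               {fraction: 0.5, requires_added_sugar_keyword: true}
  powdered_milk:             {fraction: 0.5, requires_added_sugar_keyword: true}
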