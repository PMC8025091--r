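# Category taxonomy for the packaged-food database.
#
# default_basis: the physical basis products in the category are usually
#   declared on ("solid" = per 100 g, "liquid" = per 100 ml).
# reconstitutable: products sold dry/concentrated but consumed prepared;
#   their panels are rescaled to the as-consumed form when a
#   reconstitution factor (g of product per 100 g/ml prepared) is given.
# as_consumed_basis: basis after reconstitution.
categories:
  sweetened_beverages:            {default_basis: liquid}
  sweetened_dairy_beverages:      {default_basis: liquid}
  plain_dairy:                    {default_basis: liquid}
  canned_vegetables:              {default_basis: solid}
  convenience_foods:              {default_basis: solid}
  breakfast_cereals_granola_bars: {default_basis: solid}
  cookies:                        {default_basis: solid}
  ready_to_eat_meals:             {default_basis: solid}
  processed_meats:                {default_basis: solid}
  cheeses:                        {default_basis: solid}
  breads_bakery:                  {default_basis: solid}
  candies_sweets:                 {default_basis: solid}
  sauces_condiments:              {default_basis: solid}
  instant_mixes:                  {default_basis: solid, reconstitutable: true, as_consumed_basis: liquid}
  concentrated_juices:            {default_basis: liquid, reconstitutable: true, as_consumed_basis: liquid}
  powdered_milk:                  {default_basis: solid, reconstitutable: true, as_consumed_basis: liquid}
  tea_coffee_powders:             {default_basis: solid, reconstitutable: true, as_consumed_basis: liquid}
  instant_soups:                  {default_basis: solid, reconstitutable: true, as_consumed_basis: liquid}
  table_sugar:                    {default_basis: solid}
  table_salt:                     {default_basis: solid}
  oils_fats:                      {default_basis: solid}
  butter_cream:                   {default_basis: solid}
  vinegars:                       {default_basis: liquid}
  herbs_spices:                   {default_basis: solid}
  coffees:                        {default_basis: solid}
  frozen_fruits_vegetables:       {default_basis: solid}
  frozen_chilled_meats:           {default_basis: solid}
  baby_foods:                     {default_basis: solid}
  special_dietary_foods:          {default_basis: solid}
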