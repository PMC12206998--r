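version: 1
sugar_threshold_g_per_100ml: 4.0
numeraire_index: 13
groups:
  - bottled water
  - 100% juice
  - LS soft drinks
  - HS soft drinks
  - coffee and tea
  - milk and LS dairy drinks and alternatives
  - HS dairy drinks and alternatives
  - alcoholic beverages
  - chocolate and candy
  - desserts
  - snacks
  - FVNS
  - numeraire
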