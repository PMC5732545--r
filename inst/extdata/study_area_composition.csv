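class,area_km2
farmland,1675.1
residential,330.5
open_water,23.5
total,2191.4
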