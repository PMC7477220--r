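name,lon_min,lon_max,lat_min,lat_max
Gulf of Mexico,-97,-81,18,30
Bahamas,-80,-72,22,28
Slope Sea west,-75,-70,35,41
Slope Sea east,-70,-60,36,42
Gibraltar,-8,-4,34,37
Canaries,-19,-12,26,30
Western Mediterranean,-5,9,35,44
Eastern Mediterranean,20,36,30,40
Central Mediterranean,9,20,30,42
Bay of Biscay,-9,0,43,48
Central Atlantic,-45,-20,30,50
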