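"unit"
"kg"
"g"
"mg"
"µg"
"mcg"
"lb"
"cm"
"mm"
"m"
"bpm"
"beats/min"
"/min"
"breaths/min"
"mmHg"
"kPa"
"%"
"°C"
"°F"
"mg/dL"
"g/dL"
"g/L"
"mmol/L"
"µmol/L"
"umol/L"
"IU/L"
"U/L"
"mEq/L"
"ng/mL"
"pg/mL"
"mL"
"L"
"mL/min"
"kg/m2"
"kg/m^2"
"sec"
"s"
"msec"
"ms"
"min"
"h"
"years"
"months"
"days"
"10^9/L"
"cells/µL"
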