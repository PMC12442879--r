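{
 "constants_15_33.06": {
  "K0": 0.03786792656874348,
  "K1": 1.129343049719529e-06,
  "K2": 7.100063209982141e-10,
  "KB": 1.87394097898097e-09,
  "Kw": 2.2959405329548723e-14,
  "KS": 0.1411758851854444,
  "KF": 0.0032655637651053645,
  "KSi": 2.669306772650437e-10,
  "KP1": 0.02414692882855934,
  "KP2": 8.718155836601408e-07,
  "KP3": 9.566615248705123e-10,
  "Kspa": 6.287803065860626e-07,
  "BT": 0.00039271273119164746,
  "Ca": 0.009714510694574055,
  "ST": 0.026670384355210165,
  "FT": 6.453863600278349e-05
 },
 "ta_ph_2350_8.05": {
  "dic": 2134.963693876155,
  "co2": 15.492199042632402,
  "hco3": 1963.0843082538147,
  "co3": 156.38718657970787,
  "pco2": 409.111362738825,
  "omega": 2.416145958469169
 },
 "ta_dic_2560_2030": {
  "ph": 8.506550843534363,
  "co2": 4.54955728181264,
  "hco3": 1649.47548159525,
  "co3": 375.9749611229376,
  "pco2": 120.14276180539245,
  "omega": 5.808726422351664
 }
}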