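(OTU017:1.329075208,(OTU009:0.7632096836,((((((OTU007:0.08175536225,(OTU019:0.01005619467,(OTU018:0.006798587194,OTU016:0.006798587194):0.003257607475):0.07169916758):0.1092082395,((OTU011:0.02529287118,OTU010:0.02529287118):0.1234917974,(OTU023:0.06588865006,((OTU012:0.002517272777,OTU003:0.002517272777):0.03349335859,(OTU013:0.00737450311,OTU002:0.00737450311):0.02863612826):0.02987801869):0.08289601852):0.04217893316):0.05211208812,(OTU021:0.0575146956,OTU001:0.0575146956):0.1855609943):0.07866024116,(OTU020:0.03248329255,OTU008:0.03248329255):0.2892526385):0.2364515253,(((OTU014:0.04426959914,(OTU005:0.04304421588,OTU004:0.04304421588):0.001225383254):0.2221898992,(OTU025:0.007979677404,OTU006:0.007979677404):0.2584798209):0.01604445126,(OTU024:0.1679581807,OTU015:0.1679581807):0.1145457689):0.2756835067):0.106982098,OTU022:0.6651695544):0.09804012921):0.5658655246);
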