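parameter,attribute,S,P,D,justification
filling level,carr_index,5,7,3,"Over- or under-filling the vessel degrades flowability of the blend."
filling level,drug_content,7,7,7,"Over- or under-filling the vessel prevents a homogeneous blend."
filling level,cu,7,7,7,"Fill volume drives blend homogeneity and hence uniformity."
rotational speed,carr_index,5,7,3,"Excessive or sluggish speed degrades flowability of the blend."
rotational speed,drug_content,7,7,7,"Speed drives convective mixing and hence assayed content."
rotational speed,cu,7,7,7,"Speed drives convective mixing and hence uniformity."
order of input,carr_index,3,3,3,"Charge order of API and excipients has limited effect."
order of input,drug_content,3,3,7,"Charge order of API and excipients has limited effect."
order of input,cu,3,3,7,"Charge order of API and excipients has limited effect."
blending time,carr_index,5,7,3,"Too long or too short a time degrades flowability."
blending time,drug_content,7,7,7,"Too long or too short a time leaves the blend inhomogeneous."
blending time,cu,7,7,7,"Adequate time is required for a uniform blend."
manufacturing environment,carr_index,3,3,3,"Temperature and humidity are held constant in the suite."
manufacturing environment,drug_content,3,3,7,"Temperature and humidity are held constant in the suite."
manufacturing environment,cu,3,3,7,"Temperature and humidity are held constant in the suite."
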