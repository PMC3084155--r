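item,category,unit_cost,quantity,capital_lifetime,capital_rate
Physicians,labour,15.73,3168,,
Fellows,labour,10.27,4752,,
Monitors,labour,5.29,15744,,
Education coordinator,labour,24.22,204,,
Educational workshops,labour,20.76,564.03,,
Secretary,labour,6.60,528,,
Nurse,labour,7.93,13305.60,,
Epidemiologist,labour,14.16,120,,
Coordinator's furnishings,capital,2901.14,1,5,0.05
Offices' furnishings,capital,2238.88,1,5,0.05
Sphygmomanometer,capital,90.50,7,5,0.05
Coordinator's computers,capital,1703.98,5,5,0.05
Offices' computers,capital,1703.98,4.20,5,0.05
Administrative office,land,112.09,90,,
Medical office,land,112.09,90,,
Support office,land,32.38,378,,
Workshop space,land,16.61,564.03,,
Telephone effective call,resource,0.1220571,7959.96,,
Telephone ineffective call,resource,0.0406825,7280.04,,
Brochures,resource,1.07,10000,,
Surveillance software licence,resource,4151.60,1,,
Surveillance software hardware support,resource,5579.75,1,,
Surveillance software maintenance,resource,18.52,2376,,
Surveillance software office,resource,112.09,36,,
Surveillance software development,resource,11588.72,1,,
Surveillance software server,resource,3397.26,1,,
Surveillance software computer,resource,374.83,1,,
Overhead,overhead,1.9742,8.14,,
Primary care physician visits,visit,9.63,7.40,,
Specialist visits,visit,9.63,0.74,,
Emergency ambulance service,visit,1.45,12,,
Drugs,consumption,198.99,1,,
Diagnostic and follow-up tests,consumption,36.19,1,,
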