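"npi","org_name","taxonomy","street","city","state","zip"
9862056055,"FAIRVIEW REGIONAL HOSPITAL",314000000X,7874 LAKE SHORE DR,AUSTIN,TX,73301
9909316181,"WESTBROOK MEDICAL CENTER, LLC",275N00000X,1588 ELM ST,SPOKANE,WA,99201
9954388069,"STONEBRIDGE SURGICAL CENTER, LLC",273Y00000X,2507 ELM ST,COLUMBUS,OH,43085
9954662125,"SILVER LAKE MEDICAL CENTER, LLC",314000000X,1388 RIDGE RD,ATLANTA,GA,30301
9589475851,"SILVER LAKE HEALTH SYSTEM, INC",314000000X,5744 ELM ST,DENVER,CO,80202
9664931026,"PINECREST REGIONAL HOSPITAL",275N00000X,5312 HARBOR RD,OMAHA,NE,68102
9614057039,"MAPLEWOOD SURGICAL CENTER, LLC",275N00000X,2885 CENTER ST,TAMPA,FL,33601
9345024134,"CEDAR GROVE REHABILITATION CENTER",261QE0002X,3909 HARBOR RD,PORTLAND,OR,97201
9401811788,"WESTBROOK SURGICAL CENTER, LLC",314000000X,1448 MAIN ST,AUSTIN,TX,73301
9745544616,"LAKEVIEW HEALTH SYSTEM, INC",314000000X,9884 OAK AVE,OMAHA,NE,68102
9120352866,"CEDAR GROVE COMMUNITY CLINIC",314000000X,7594 PARK BLVD,BOISE,ID,83701
9991875599,"MAPLEWOOD REHABILITATION CENTER",282N00000X,6080 CENTER ST,GLENDALE,CA,91201
9068541728,"EASTGATE REHABILITATION CENTER",314000000X,3456 RIDGE RD,PHOENIX,AZ,85001
9286880973,"PINECREST REHABILITATION CENTER",273Y00000X,6347 PARK BLVD,ALBANY,NY,12207
9410503970,"BAYSIDE SURGICAL CENTER, LLC",314000000X,2084 ELM ST,TAMPA,FL,33601
9057092774,"REDWOOD HEALTH SYSTEM, INC",283Q00000X,4603 GLENOAKS BLVD,DENVER,CO,80202
9372523883,"WILLOW CREEK HEALTH SYSTEM, INC",275N00000X,4727 HARBOR RD,ALBANY,NY,12207
9820130489,"OAKDALE HEALTH SYSTEM, INC",273Y00000X,3744 PARK BLVD,OMAHA,NE,68102
9447600518,"SOUTHPOINT COMMUNITY CLINIC",282N00000X,3886 SUNSET DR,DENVER,CO,80202
9674269219,"NORTHSIDE COMMUNITY CLINIC",275N00000X,8587 GLENOAKS BLVD,ATLANTA,GA,30301
9510394023,"BLUE RIDGE HEALTH SYSTEM, INC",282N00000X,1239 LAKE SHORE DR,ATLANTA,GA,30301
9864870271,"SUMMIT REGIONAL HOSPITAL",273Y00000X,6796 SUNSET DR,BOISE,ID,83701
9688503876,"HARBORVIEW COMMUNITY CLINIC",314000000X,5199 RIDGE RD,RALEIGH,NC,27601
9139121005,"BAYSIDE REHABILITATION CENTER",314000000X,2575 GLENOAKS BLVD,BOISE,ID,83701
9418713134,"OAKDALE COMMUNITY CLINIC",283Q00000X,3192 RIDGE RD,ATLANTA,GA,30301
9910489795,"SUMMIT SURGICAL CENTER, LLC",283Q00000X,8364 RIDGE RD,MADISON,WI,53703
9424664453,"EASTGATE COMMUNITY CLINIC",283Q00000X,9725 GLENOAKS BLVD,COLUMBUS,OH,43085
9958356138,"WILLOW CREEK MEDICAL CENTER, LLC",283Q00000X,5899 HARBOR RD,PHOENIX,AZ,85001
9856493470,"CEDAR GROVE MEDICAL CENTER, LLC",275N00000X,1021 HARBOR RD,BOISE,ID,83701
9097420027,"FAIRVIEW MEDICAL CENTER, LLC",282N00000X,8812 HARBOR RD,MADISON,WI,53703
9487329549,"GLENWOOD COMMUNITY CLINIC",273Y00000X,6989 RIDGE RD,GLENDALE,CA,91201
9459736010,"STONEBRIDGE REGIONAL HOSPITAL",314000000X,7411 ELM ST,ALBANY,NY,12207
9457928338,"HARBORVIEW HEALTH SYSTEM, INC",273Y00000X,6563 PARK BLVD,PORTLAND,OR,97201
9748309066,"OAKDALE REHABILITATION CENTER",275N00000X,2688 LAKE SHORE DR,ATLANTA,GA,30301
9719583525,"HILLTOP COMMUNITY CLINIC",314000000X,1324 CENTER ST,GLENDALE,CA,91201
9665161169,"NORTHSIDE REHABILITATION CENTER",275N00000X,9248 CENTER ST,TAMPA,FL,33601
9094940787,"LAKEVIEW COMMUNITY CLINIC",282N00000X,3028 OAK AVE,PORTLAND,OR,97201
9483664410,"HARBORVIEW REGIONAL HOSPITAL",282N00000X,8884 RIDGE RD,ATLANTA,GA,30301
9283899257,"GLENWOOD SURGICAL CENTER, LLC",314000000X,7104 SUNSET DR,PORTLAND,OR,97201
9201566491,"LAKEVIEW REGIONAL HOSPITAL",282N00000X,2650 RIDGE RD,BOISE,ID,83701
9857691767,"BLUE RIDGE REHABILITATION CENTER",275N00000X,4772 LAKE SHORE DR,OMAHA,NE,68102
9431039129,"REDWOOD MEDICAL CENTER, LLC",282N00000X,6378 MAIN ST,OMAHA,NE,68102
9278614687,"MAPLEWOOD REGIONAL HOSPITAL",283Q00000X,6958 PARK BLVD,TAMPA,FL,33601
9641017840,"BIRCHWOOD REHABILITATION CENTER",282N00000X,7030 CENTER ST,COLUMBUS,OH,43085
9287694100,"SUMMIT REHABILITATION CENTER",275N00000X,4313 HARBOR RD,GLENDALE,CA,91201
9383101638,"WILLOW CREEK COMMUNITY CLINIC",275N00000X,876 HARBOR RD,ALBANY,NY,12207
9151885016,"FAIRVIEW REHABILITATION CENTER",283Q00000X,4257 GLENOAKS BLVD,DENVER,CO,80202
9648795810,"VALLEY HEALTH SYSTEM, INC",282N00000X,2433 HARBOR RD,ATLANTA,GA,30301
9351828329,"WESTBROOK REGIONAL HOSPITAL",282N00000X,5580 HARBOR RD,COLUMBUS,OH,43085
9805754410,"EASTGATE HEALTH SYSTEM, INC",273Y00000X,5788 MAIN ST,GLENDALE,CA,91201
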