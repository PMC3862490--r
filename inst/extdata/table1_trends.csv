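bcr,species,method,estimate,lo,hi
Appalachian Mountains,Carolina wren,CAR,1.9,0.5,3.2
Appalachian Mountains,Carolina wren,nonspatial,2.2,1.0,3.45
Appalachian Mountains,Cerulean warbler,CAR,-2.8,-7.9,2.4
Appalachian Mountains,Cerulean warbler,nonspatial,-1.0,-3.1,1.7
Appalachian Mountains,Red-bellied woodpecker,CAR,3.4,2.1,4.7
Appalachian Mountains,Red-bellied woodpecker,nonspatial,3.8,2.9,4.6
Atlantic Northern Forest,Carolina wren,CAR,8.6,0.2,17.7
Atlantic Northern Forest,Carolina wren,nonspatial,11.6,-10.7,33.4
Atlantic Northern Forest,Red-bellied woodpecker,CAR,11,5.3,17
Atlantic Northern Forest,Red-bellied woodpecker,nonspatial,19.7,7.4,30.5
Boreal Hardwood Transition,Cerulean warbler,CAR,6.6,-12.3,29.1
Boreal Hardwood Transition,Cerulean warbler,nonspatial,-17.5,-62.0,10.7
Boreal Hardwood Transition,Red-bellied woodpecker,CAR,6.7,1.5,12.1
Boreal Hardwood Transition,Red-bellied woodpecker,nonspatial,9.7,3.6,15.5
Central Hardwoods,Carolina wren,CAR,2.1,0.7,3.5
Central Hardwoods,Carolina wren,nonspatial,2.6,1.4,3.9
Central Hardwoods,Cerulean warbler,CAR,3.8,-5.3,13.3
Central Hardwoods,Cerulean warbler,nonspatial,-2.1,-4.7,0.9
Central Hardwoods,Red-bellied woodpecker,CAR,0.1,-1.1,1.4
Central Hardwoods,Red-bellied woodpecker,nonspatial,-0.04,-1.0,0.9
Central Mixed Grass Prairie,Carolina wren,CAR,3.1,-1.9,8.2
Central Mixed Grass Prairie,Carolina wren,nonspatial,3.1,-2.0,8.1
Central Mixed Grass Prairie,Red-bellied woodpecker,CAR,1.8,-1.5,5
Central Mixed Grass Prairie,Red-bellied woodpecker,nonspatial,2.8,1.1,4.7
Eastern Tallgrass Prairie,Carolina wren,CAR,4.7,2.3,7.1
Eastern Tallgrass Prairie,Carolina wren,nonspatial,5.5,3.2,7.8
Eastern Tallgrass Prairie,Cerulean warbler,CAR,0.1,-10,11.5
Eastern Tallgrass Prairie,Cerulean warbler,nonspatial,-3.8,-15.4,13.5
Eastern Tallgrass Prairie,Red-bellied woodpecker,CAR,2.9,1.4,4.3
Eastern Tallgrass Prairie,Red-bellied woodpecker,nonspatial,2.0,0.9,3.1
Edwards Plateau,Carolina wren,CAR,1.3,-4.4,6.3
Edwards Plateau,Carolina wren,nonspatial,0.5,-3.5,4.0
Edwards Plateau,Red-bellied woodpecker,CAR,-2.7,-9,3.7
Edwards Plateau,Red-bellied woodpecker,nonspatial,0.3,-12.6,14.6
Gulf Coastal Prairie,Carolina wren,CAR,1.1,-2.7,5.1
Gulf Coastal Prairie,Carolina wren,nonspatial,5.8,3.0,9.4
Gulf Coastal Prairie,Red-bellied woodpecker,CAR,-1,-4.4,2.7
Gulf Coastal Prairie,Red-bellied woodpecker,nonspatial,2.3,0.1,4.5
Lower Great Lakes/St. Lawrence Plain,Carolina wren,CAR,2.4,-2.1,7.1
Lower Great Lakes/St. Lawrence Plain,Carolina wren,nonspatial,3.1,-2.1,8.3
Lower Great Lakes/St. Lawrence Plain,Cerulean warbler,CAR,-8.3,-18,3.5
Lower Great Lakes/St. Lawrence Plain,Cerulean warbler,nonspatial,-1.6,-6.4,3.0
Lower Great Lakes/St. Lawrence Plain,Red-bellied woodpecker,CAR,6.4,3.5,9.4
Lower Great Lakes/St. Lawrence Plain,Red-bellied woodpecker,nonspatial,6.7,5.0,8.5
Mississippi Alluvial Valley,Carolina wren,CAR,1.3,-0.4,2.9
Mississippi Alluvial Valley,Carolina wren,nonspatial,1.3,-0.2,2.7
Mississippi Alluvial Valley,Red-bellied woodpecker,CAR,-3.1,-4.8,-1.4
Mississippi Alluvial Valley,Red-bellied woodpecker,nonspatial,1.2,-0.5,2.7
New England/Mid-Atlantic Coast,Carolina wren,CAR,5.3,3.8,6.8
New England/Mid-Atlantic Coast,Carolina wren,nonspatial,4.7,3.2,6.4
New England/Mid-Atlantic Coast,Cerulean warbler,CAR,-7.9,-27.2,15.6
New England/Mid-Atlantic Coast,Cerulean warbler,nonspatial,3.6,-24.4,21.1
New England/Mid-Atlantic Coast,Red-bellied woodpecker,CAR,5,3,7.1
New England/Mid-Atlantic Coast,Red-bellied woodpecker,nonspatial,4.1,2.7,5.6
Oaks And Prairies,Carolina wren,CAR,-0.3,-2.5,1.9
Oaks And Prairies,Carolina wren,nonspatial,-0.7,-2.7,1.2
Oaks And Prairies,Red-bellied woodpecker,CAR,4.8,2.4,7.4
Oaks And Prairies,Red-bellied woodpecker,nonspatial,2.6,0.8,4.6
Peninsular Florida,Carolina wren,CAR,0.2,-1.5,1.9
Peninsular Florida,Carolina wren,nonspatial,-0.2,-1.2,0.7
Peninsular Florida,Red-bellied woodpecker,CAR,-0.9,-2.5,0.7
Peninsular Florida,Red-bellied woodpecker,nonspatial,-0.7,-2.0,0.6
Piedmont,Carolina wren,CAR,1.3,0,2.6
Piedmont,Carolina wren,nonspatial,0.8,-0.3,2.0
Piedmont,Cerulean warbler,CAR,-3.6,-15.3,9.5
Piedmont,Cerulean warbler,nonspatial,-0.3,-7.7,7.7
Piedmont,Red-bellied woodpecker,CAR,1.6,0.2,3.1
Piedmont,Red-bellied woodpecker,nonspatial,1.4,0.4,2.4
Prairie Hardwood Transition,Carolina wren,CAR,5.3,-2.1,13.2
Prairie Hardwood Transition,Carolina wren,nonspatial,5.1,-6.2,13.9
Prairie Hardwood Transition,Cerulean warbler,CAR,6.7,-6.2,21.7
Prairie Hardwood Transition,Cerulean warbler,nonspatial,-1.1,-5.4,7.3
Prairie Hardwood Transition,Red-bellied woodpecker,CAR,5.4,3.6,7.3
Prairie Hardwood Transition,Red-bellied woodpecker,nonspatial,4.9,3.8,6.2
Prairie Potholes,Red-bellied woodpecker,CAR,3.8,-2.6,10.5
Prairie Potholes,Red-bellied woodpecker,nonspatial,5.1,1.4,9.1
Southeastern Coastal Plain,Carolina wren,CAR,0.6,-0.4,1.6
Southeastern Coastal Plain,Carolina wren,nonspatial,0.5,-0.2,1.1
Southeastern Coastal Plain,Cerulean warbler,CAR,6.7,-14.8,32.1
Southeastern Coastal Plain,Cerulean warbler,nonspatial,-3.0,-53.0,105.1
Southeastern Coastal Plain,Red-bellied woodpecker,CAR,1.6,0.6,2.5
Southeastern Coastal Plain,Red-bellied woodpecker,nonspatial,1.0,0.5,1.5
Tamaulipan Brushlands,Carolina wren,CAR,-6.9,-18.1,4.4
Tamaulipan Brushlands,Carolina wren,nonspatial,6.9,1.3,14.0
West Gulf Coastal Plain/Ouachitas,Carolina wren,CAR,0.5,-0.8,1.8
West Gulf Coastal Plain/Ouachitas,Carolina wren,nonspatial,0.4,-0.9,1.6
West Gulf Coastal Plain/Ouachitas,Cerulean warbler,CAR,7.8,-26.3,56.2
West Gulf Coastal Plain/Ouachitas,Cerulean warbler,nonspatial,-15.3,-27.6,-0.4
West Gulf Coastal Plain/Ouachitas,Red-bellied woodpecker,CAR,1,-0.7,2.7
West Gulf Coastal Plain/Ouachitas,Red-bellied woodpecker,nonspatial,0.7,-0.3,1.6
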